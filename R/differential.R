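#' Invert the trigamma function
#'
#' Newton iteration for `trigamma(y) = x`, used when matching moments of log
#' residual variances to a scaled-F distribution. Follows the standard
#' large/small-argument starting values; converges in a handful of steps.
#'
#' @param x positive target value(s).
#' @param tol convergence tolerance on the relative step.
#' @return `y` with `trigamma(y) = x`.
#' @keywords internal
trigamma_inverse <- function(x, tol = 1e-8) {
  sapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (it in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2)
      y <- y + dif
      if (abs(dif / y) < tol) break
    }
    y
  })
}

#' Estimate the variance prior by moment matching
#'
#' Under the empirical-Bayes model the per-protein residual variances s^2
#' follow a scaled F distribution, s^2 ~ s0^2 * F(df, d0). Matching the mean
#' and variance of log(s^2) through digamma/trigamma identities yields
#' closed-form moment estimates of the prior degrees of freedom `d0` and
#' prior variance `s0_sq`. When the spread of log variances is no larger
#' than expected from sampling alone, `d0` is effectively infinite and is
#' capped at a large finite value.
#'
#' @param s2 per-protein residual variances (positive; zeros are handled by
#'   the caller).
#' @param df residual degrees of freedom shared by all proteins.
#' @param d0_max cap for the prior degrees of freedom.
#' @return list with `d0` and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, df, d0_max = 1e6) {
  stopifnot(df >= 1, all(s2 > 0))
  if (length(s2) < 2) return(list(d0 = 0, s0_sq = mean(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ev <- stats::var(e) - trigamma(df / 2)
  if (is.na(ev) || ev <= 0) {
    d0 <- d0_max
    s0_sq <- exp(mean(e))
  } else {
    d0 <- 2 * trigamma_inverse(ev)
    if (d0 > d0_max) d0 <- d0_max
    s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Per protein, a pooled-variance two-group comparison in which the residual
#' variance is shrunk towards an ensemble prior estimated from all proteins:
#' s_tilde^2 = (d0 * s0^2 + df * s^2) / (d0 + df), with the moderated
#' statistic t = lfc / (s_tilde * sqrt(1/nA + 1/nB)) referred to a t
#' distribution on df + d0 degrees of freedom. Borrowing strength across the
#' ensemble stabilises the variance estimates at the small group sizes
#' typical of cord-blood contrasts.
#'
#' With a single protein there is no ensemble and `d0` is 0, reducing to the
#' ordinary pooled t-test. When every protein has zero residual variance the
#' prior cannot be estimated; the unmoderated statistic is returned with a
#' warning.
#'
#' @param a,b numeric matrices of imputed log2 intensities (proteins x
#'   samples) for groups A and B, same protein rows; each group needs at
#'   least 2 samples. The log fold change is `rowMeans(a) - rowMeans(b)`.
#' @param d0,s0_sq optional prior overrides; `NULL` (default) estimates both
#'   from the data via [fit_variance_prior()].
#' @return a data.frame with columns `protein_id`, `lfc`, `s_sq`,
#'   `s_tilde_sq`, `t_mod`, `df_total`, `p`, `p_adj`, plus the hyperparameters
#'   as attributes `d0` and `s0_sq`.
#' @export
moderated_ttest <- function(a, b, d0 = NULL, s0_sq = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("groups must share the protein set")
  na <- ncol(a); nb <- ncol(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 samples")
  if (anyNA(a) || anyNA(b)) stop("moderated t expects imputed (complete) data")
  ids <- rownames(a)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(a)))

  lfc <- rowMeans(a) - rowMeans(b)
  df <- na + nb - 2
  ssa <- rowSums((a - rowMeans(a))^2)
  ssb <- rowSums((b - rowMeans(b))^2)
  s2 <- (ssa + ssb) / df

  if (is.null(d0) || is.null(s0_sq)) {
    pos <- s2 > 0
    if (!any(pos)) {
      warning("zero residual variance in every protein; ",
              "falling back to the unmoderated t statistic")
      d0 <- 0; s0_sq <- 0
    } else if (nrow(a) == 1) {
      d0 <- 0; s0_sq <- s2
    } else {
      prior <- fit_variance_prior(s2[pos], df)
      d0 <- prior$d0; s0_sq <- prior$s0_sq
    }
  }

  s_tilde2 <- if (d0 > 0) (d0 * s0_sq + df * s2) / (d0 + df) else s2
  se <- sqrt(s_tilde2 * (1 / na + 1 / nb))
  t_mod <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  df_total <- df + d0
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  res <- data.frame(protein_id = ids, lfc = lfc, s_sq = s2,
                    s_tilde_sq = s_tilde2, t_mod = t_mod,
                    df_total = df_total, p = p,
                    stringsAsFactors = FALSE)
  res$p_adj <- bh_adjust(res$p)
  rownames(res) <- NULL
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0_sq
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted p-values in input order: with p-values sorted ascending,
#'   `adj_(i) = min_{j >= i} p_(j) * m / j`, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Flag significant proteins
#'
#' Both boundaries are strict, matching the published decision rule:
#' adjusted p below `alpha` and absolute log fold change above `lfc_min`.
#'
#' @param results a [moderated_ttest()] result.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc_min absolute LFC threshold (default 1).
#' @return `results` with a logical `significant` column appended.
#' @export
call_significant <- function(results, alpha = 0.05, lfc_min = 1) {
  stopifnot(all(c("p_adj", "lfc") %in% names(results)))
  results$significant <- results$p_adj < alpha & abs(results$lfc) > lfc_min
  results
}

#' Qualitative presence comparison between cohorts
#'
#' Partitions the union of the two cohorts' retained protein sets into
#' shared, infant-only and adult-only sets. Purely qualitative: the cohorts'
#' intensity distributions differ too much for a quantitative contrast.
#'
#' @param infant_retained character vector of protein ids retained for the
#'   infant cohort, or a [filter_completeness()] report (in which case
#'   `adult_retained` is taken from the same report).
#' @param adult_retained character vector of protein ids retained for adults.
#' @return list with character vectors `shared`, `infant_only`, `adult_only`
#'   and a named `counts` vector.
#' @export
presence_sets <- function(infant_retained, adult_retained = NULL) {
  if (is.data.frame(infant_retained)) {
    report <- infant_retained
    stopifnot(all(c("protein_id", "retained_infant", "retained_adult") %in%
                    names(report)))
    adult_retained <- report$protein_id[report$retained_adult]
    infant_retained <- report$protein_id[report$retained_infant]
  }
  shared <- intersect(infant_retained, adult_retained)
  infant_only <- setdiff(infant_retained, adult_retained)
  adult_only <- setdiff(adult_retained, infant_retained)
  list(shared = shared, infant_only = infant_only, adult_only = adult_only,
       counts = c(shared = length(shared), infant_only = length(infant_only),
                  adult_only = length(adult_only)))
}
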