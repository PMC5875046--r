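#' Per-condition means with t confidence intervals
#'
#' Estimates the mean of a metric per algorithm x dose (x pitch) condition,
#' optionally on the natural-log scale (the conventional transform for noise
#' and MTF, which are positive and right-skewed). With balanced single-level
#' replication this is the sample mean with a `t`-based CI from the
#' between-replicate variance - the closed-form behaviour a mixed model
#' degenerates to on balanced replicate data.
#'
#' @param records data.frame with columns `algorithm`, `dose`, optionally
#'   `pitch` and `replicate`, and `value`.
#' @param log_scale analyze `log(value)` (values must be positive).
#' @param conf confidence level (default 0.95).
#' @return a `condition_means` data.frame: `algorithm`, `dose`, (`pitch`),
#'   `n`, `estimate`, `sd`, `se`, `df`, `lcl`, `ucl`; attribute `scale` is
#'   `"log"` or `"raw"`. Single-replicate conditions get `NA` intervals and
#'   a warning.
#' @export
estimate_condition_means <- function(records, log_scale = TRUE,
                                     conf = 0.95) {
  stopifnot(all(c("algorithm", "dose", "value") %in% names(records)))
  v <- records$value
  if (log_scale) {
    if (any(v <= 0)) stop("log-scale analysis requires positive values")
    v <- log(v)
  }
  has_pitch <- "pitch" %in% names(records)
  key <- if (has_pitch) {
    interaction(records$algorithm, records$dose, records$pitch, drop = TRUE)
  } else {
    interaction(records$algorithm, records$dose, drop = TRUE)
  }
  rows <- lapply(levels(key), function(cell) {
    i <- which(key == cell)
    n <- length(i)
    m <- mean(v[i])
    s <- if (n > 1) stats::sd(v[i]) else NA_real_
    se <- s / sqrt(n)
    crit <- if (n > 1) stats::qt(1 - (1 - conf) / 2, n - 1) else NA_real_
    out <- data.frame(algorithm = records$algorithm[i[1]],
                      dose = records$dose[i[1]], n = n, estimate = m,
                      sd = s, se = se, df = n - 1,
                      lcl = m - crit * se, ucl = m + crit * se)
    if (has_pitch) out$pitch <- records$pitch[i[1]]
    out
  })
  out <- do.call(rbind, rows)
  if (any(out$n < 2)) {
    warning("conditions with a single replicate have undefined intervals")
  }
  structure(out, scale = if (log_scale) "log" else "raw", conf = conf,
            class = c("condition_means", "data.frame"))
}

#' Contrasts of every condition against a reference cell
#'
#' Differences `condition mean - reference mean` on the analysis scale, with
#' unadjusted t confidence intervals and Dunnett-adjusted p-values for the
#' family of contrasts against the shared reference (conventionally the
#' best-case low-dose cell, e.g. MBIR at 1 mGy). Two input forms are
#' supported:
#' * a [estimate_condition_means()] table carrying `sd`/`n` - the pooled
#'   within-condition variance drives SEs, t statistics and adjusted
#'   p-values (balanced-design contrast correlation 0.5);
#' * a published-style summary table with only `estimate`, `lcl`, `ucl` -
#'   SEs are recovered from the CI half-widths (normal critical value) and
#'   p-values use the normal reference distribution.
#'
#' When a `pitch` column is present the reference is matched within pitch.
#'
#' @param means a `condition_means`-shaped data.frame.
#' @param reference list with `algorithm` and `dose` naming the reference.
#' @param conf confidence level for the (unadjusted) interval.
#' @param rho common contrast correlation for the Dunnett adjustment
#'   (default 0.5, the balanced shared-reference value).
#' @param adjust compute Dunnett-adjusted p-values.
#' @return a `comparison_table` data.frame: contrast rows with `estimate`
#'   (difference), `lcl`, `ucl`, `adjusted_p`.
#' @export
difference_vs_reference <- function(means,
                                    reference = list(algorithm = "MBIR",
                                                     dose = 1),
                                    conf = 0.95, rho = 0.5, adjust = TRUE) {
  stopifnot(all(c("algorithm", "dose", "estimate") %in% names(means)))
  has_pitch <- "pitch" %in% names(means)
  groups <- if (has_pitch) split(seq_len(nrow(means)), means$pitch) else
    list(seq_len(nrow(means)))
  out <- lapply(groups, function(i) {
    m <- means[i, , drop = FALSE]
    ref_i <- which(m$algorithm == reference$algorithm &
                     abs(m$dose - reference$dose) < 1e-9)
    if (length(ref_i) != 1L) {
      stop("reference cell ", reference$algorithm, " @ ", reference$dose,
           " mGy is missing (or duplicated)")
    }
    contrast_block(m, ref_i, conf, rho, adjust)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, reference = reference, conf = conf,
            scale = attr(means, "scale"),
            class = c("comparison_table", "data.frame"))
}

contrast_block <- function(m, ref_i, conf, rho, adjust) {
  k <- nrow(m) - 1L
  diff <- m$estimate - m$estimate[ref_i]
  pooled <- all(c("sd", "n") %in% names(m)) && !anyNA(m$sd)
  if (pooled) {
    dfs <- m$n - 1
    s2 <- sum(dfs * m$sd^2) / sum(dfs)
    df <- sum(dfs)
    se <- sqrt(s2 * (1 / m$n + 1 / m$n[ref_i]))
    crit <- stats::qt(1 - (1 - conf) / 2, df)
  } else {
    if (!all(c("lcl", "ucl") %in% names(m))) {
      stop("means table needs either sd/n or lcl/ucl columns")
    }
    z <- stats::qnorm(1 - (1 - conf) / 2)
    se_i <- (m$ucl - m$lcl) / (2 * z)
    se <- sqrt(se_i^2 + se_i[ref_i]^2)
    df <- Inf
    crit <- z
  }
  se[ref_i] <- 0
  t_stat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf))
  adj <- rep(NA_real_, nrow(m))
  if (adjust && k >= 1) {
    adj[-ref_i] <- dunnett_adjust(t_stat[-ref_i], df = df, rho = rho)
  }
  out <- data.frame(algorithm = m$algorithm, dose = m$dose,
                    estimate = diff,
                    lcl = diff - crit * se, ucl = diff + crit * se,
                    adjusted_p = adj,
                    is_reference = seq_len(nrow(m)) == ref_i)
  if ("pitch" %in% names(m)) out$pitch <- m$pitch
  out
}

#' Dunnett-adjusted p-values for contrasts against a shared reference
#'
#' Two-sided single-step adjustment: for each observed statistic `t`, the
#' adjusted p-value is `P(max_j |T_j| >= |t|)` under the equicorrelated
#' k-dimensional multivariate t null (correlation `rho`, `df` degrees of
#' freedom). The probability is computed by deterministic quadrature:
#' Gauss-Hermite nodes over the shared normal factor crossed with a
#' quantile-midpoint rule over the chi-distributed scale. `k = 1` reduces
#' exactly to the unadjusted two-sided t (or normal) p-value.
#'
#' @param t_stats observed t statistics (the family is their joint set).
#' @param df degrees of freedom (`Inf` for the normal case).
#' @param rho common correlation in `[0, 1)`; 0.5 is the balanced
#'   shared-reference value.
#' @param k family size (defaults to `length(t_stats)`).
#' @param n_nodes,n_scale quadrature resolution.
#' @return adjusted p-values, always >= the unadjusted ones.
#' @export
dunnett_adjust <- function(t_stats, df, rho = 0.5, k = length(t_stats),
                           n_nodes = 96L, n_scale = 256L) {
  if (!is.finite(rho) || rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (!(is.infinite(df) || df > 0)) stop("df must be positive (or Inf)")
  stopifnot(k >= 1)
  p_unadj <- function(t) {
    if (is.infinite(df)) 2 * stats::pnorm(-abs(t)) else
      2 * stats::pt(-abs(t), df)
  }
  if (k == 1L) {
    return(vapply(t_stats, p_unadj, 0))
  }
  gh <- gauss_hermite_prob(n_nodes)
  u <- (seq_len(n_scale) - 0.5) / n_scale
  w_scale <- if (is.finite(df)) sqrt(stats::qchisq(u, df) / df) else 1
  sr <- sqrt(rho)
  sc <- sqrt(1 - rho)
  vapply(t_stats, function(t) {
    t <- abs(t)
    if (!is.finite(t)) return(0)
    tot <- 0
    for (w in w_scale) {
      inner <- (stats::pnorm((t * w - sr * gh$nodes) / sc) -
                  stats::pnorm((-t * w - sr * gh$nodes) / sc))^k
      tot <- tot + sum(gh$weights * inner)
    }
    max(0, min(1, 1 - tot / length(w_scale)))
  }, 0)
}

# probabilist's Gauss-Hermite rule (nodes for N(0,1), weights sum to 1),
# via the Golub-Welsch eigen decomposition of the Jacobi matrix
gauss_hermite_prob <- function(n) {
  i <- seq_len(n - 1L)
  a <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- a
  J[cbind(i + 1L, i)] <- a
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord] * sqrt(2), weights = (e$vectors[1, ord])^2)
}

#' MTF ratio table against a reference algorithm
#'
#' Per pitch x dose cell, the mean log-MTF difference of each algorithm
#' against the reference (FBP) is back-transformed to a ratio with a
#' back-transformed confidence interval and a Dunnett-adjusted p-value over
#' the family of algorithm contrasts in that cell. A ratio above 1 means
#' higher MTF (better resolution) than the reference.
#'
#' @param records data.frame with `algorithm`, `dose`, `pitch`, `replicate`,
#'   `value` (MTF at the target frequency, positive).
#' @param reference_algorithm reference label (default `"FBP"`).
#' @param conf confidence level.
#' @param rho contrast correlation for the Dunnett adjustment.
#' @return a `comparison_table`-style data.frame with columns `pitch`,
#'   `dose`, `ratio_label`, `estimate` (ratio), `lcl`, `ucl`, `adjusted_p`.
#' @export
mtf_ratio_table <- function(records, reference_algorithm = "FBP",
                            conf = 0.95, rho = 0.5) {
  stopifnot(all(c("algorithm", "dose", "value") %in% names(records)))
  if (any(records$value <= 0)) stop("MTF values must be positive")
  if (!"pitch" %in% names(records)) records$pitch <- NA_real_
  lv <- log(records$value)
  cell <- interaction(records$pitch, records$dose, drop = TRUE)
  out <- lapply(levels(cell), function(cl) {
    i <- which(cell == cl)
    algs <- unique(records$algorithm[i])
    if (!reference_algorithm %in% algs) {
      stop("cell pitch/dose = ", cl, " lacks the reference algorithm ",
           reference_algorithm)
    }
    g <- split(lv[i], records$algorithm[i])
    ns <- lengths(g)
    mns <- vapply(g, mean, 0)
    dfs <- ns - 1
    s2 <- if (sum(dfs) > 0) {
      sum(vapply(g, function(x) sum((x - mean(x))^2), 0)) / sum(dfs)
    } else NA_real_
    df <- sum(dfs)
    others <- setdiff(names(g), reference_algorithm)
    diff <- mns[others] - mns[[reference_algorithm]]
    se <- sqrt(s2 * (1 / ns[others] + 1 / ns[[reference_algorithm]]))
    t_stat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf))
    crit <- stats::qt(1 - (1 - conf) / 2, df)
    adj <- if (df > 0 && !is.na(s2) && s2 > 0) {
      dunnett_adjust(t_stat, df = df, rho = rho)
    } else {
      ifelse(diff == 0, 1, 0)
    }
    data.frame(pitch = records$pitch[i[1]], dose = records$dose[i[1]],
               ratio_label = paste0(others, "/", reference_algorithm),
               estimate = exp(diff),
               lcl = exp(diff - crit * se), ucl = exp(diff + crit * se),
               adjusted_p = adj)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, reference = reference_algorithm, conf = conf,
            scale = "ratio", class = c("comparison_table", "data.frame"))
}

#' Bundled benchmark condition-mean tables
#'
#' Published per-condition summary tables (log-noise and CNR means with 95%
#' confidence limits by reconstruction algorithm and CTDIvol) from a
#' Catphan 600 iterative-reconstruction dose study, shipped as plain TSV.
#' These serve as inputs to [difference_vs_reference()] for reproducing the
#' corresponding published contrast tables, and as calibration anchors for
#' the generator defaults. The `VEO` label is the product name of the MBIR
#' algorithm in those tables.
#'
#' @param metric `"log_noise"` or `"cnr"`.
#' @return data.frame with `algorithm`, `dose`, `estimate`, `lcl`, `ucl`.
#' @export
catphan_benchmark_means <- function(metric = c("log_noise", "cnr")) {
  metric <- match.arg(metric)
  f <- system.file("extdata",
                   paste0("benchmark_", metric, "_means.tsv"),
                   package = "ctiq", mustWork = TRUE)
  out <- utils::read.delim(f, stringsAsFactors = FALSE)
  structure(out, scale = if (metric == "log_noise") "log" else "raw",
            class = c("condition_means", "data.frame"))
}
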