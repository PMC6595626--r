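#' Single-component PLS VIP scores for a two-group comparison
#'
#' With one latent component the variable-importance-in-projection
#' formula reduces to `VIP_j = sqrt(P) * |w_j|`, where
#' `w = X'y / ||X'y||` is the unit loading weight built from the
#' column-autoscaled data matrix and the centered group labels, and `P`
#' is the number of variables. By construction `sum(VIP^2) = P`.
#'
#' @param X samples x metabolites matrix (two groups).
#' @param y group labels (two levels; any coding).
#' @param autoscale center and unit-scale columns first (default
#'   `TRUE`; set `FALSE` if `X` is already autoscaled).
#' @return list: `vip` (named, >= 0), `w` (unit loading weights),
#'   `dropped` (zero-variance metabolites, removed with a warning).
#' @export
plsVIP <- function(X, y, autoscale = TRUE) {
  X <- as.matrix(X)
  if (length(unique(y)) != 2)
    stop(germError("y must have exactly two groups", "germDataError"))
  if (min(table(y)) < 2)
    stop(germError("both groups need >= 2 samples", "germDataError"))
  yc <- as.numeric(factor(y)) - mean(as.numeric(factor(y)))
  sds <- apply(X, 2, sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning(sprintf("dropping %d zero-variance metabolite(s)",
                    length(dropped)))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (autoscale) X <- scale(X)
  w <- as.numeric(crossprod(X, yc))
  w <- w / sqrt(sum(w^2))
  P <- ncol(X)
  list(vip = setNames(sqrt(P) * abs(w), colnames(X)),
       w = setNames(w, colnames(X)), dropped = dropped)
}

#' Equal-variance two-sample Student's t-test
#'
#' Pooled-variance t with `df = n1 + n2 - 2`, two-sided. Degenerate
#' inputs: zero pooled variance with equal means gives `p = 1`; with
#' unequal means the p-value is the 0-limit (smallest positive double),
#' flagged by the `degenerate` element.
#'
#' @param group1,group2 numeric vectors, each of length >= 2.
#' @return list: `statistic`, `df`, `p`, `degenerate`.
#' @export
twoSampleT <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2)
    stop(germError("each group needs >= 2 values", "germDataError"))
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(group1) + (n2 - 1) * var(group2)) / df
  dm <- mean(group1) - mean(group2)
  if (sp2 == 0) {
    if (dm == 0) return(list(statistic = 0, df = df, p = 1,
                             degenerate = TRUE))
    return(list(statistic = sign(dm) * Inf, df = df,
                p = .Machine$double.xmin, degenerate = TRUE))
  }
  t <- dm / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df),
       degenerate = FALSE)
}

#' Two-step metabolite significance calls
#'
#' For each stage against the reference (stage 1, the dry seed, by
#' default): (1) a single-component PLS VIP filter across all
#' metabolites, then (2) Student's t-test per metabolite. A metabolite
#' is significant at a stage iff `VIP > vipMin` (strict) AND
#' `p < alpha` (strict). Abundances are log2-transformed before
#' autoscaling, matching the multiplicative noise model; direction is
#' the sign of the mean log2 difference.
#'
#' @param metab a [StageExperiment-class] of metabolite abundances.
#' @param reference reference stage (default 1).
#' @param vipMin VIP threshold (default 1.0, strict `>`).
#' @param alpha t-test threshold (default 0.05, strict `<`).
#' @param mode `"reference"` (every stage vs `reference`) or
#'   `"successive"`.
#' @return data.frame: `metabolite`, `stage`, `vip`, `p`, `direction`,
#'   `significant` (one row per metabolite and non-reference stage).
#' @export
callChangedMetabolites <- function(metab, reference = 1, vipMin = 1.0,
                                   alpha = 0.05,
                                   mode = c("reference", "successive")) {
  mode <- match.arg(mode)
  st <- stages(metab)
  if (!reference %in% st)
    stop(germError("reference stage absent", "germDataError"))
  x <- log2(SummarizedExperiment::assay(metab))
  lv <- sort(unique(st))
  pairs <- if (mode == "reference")
    lapply(setdiff(lv, reference), function(s) c(s, reference))
  else lapply(seq_len(length(lv) - 1L), function(i) c(lv[i + 1], lv[i]))
  out <- list()
  for (p in pairs) {
    cols <- st %in% p
    Xp <- t(x[, cols, drop = FALSE])
    yp <- st[cols]
    vip <- plsVIP(Xp, yp)$vip
    for (m in rownames(x)) {
      g1 <- x[m, st == p[1]]; g2 <- x[m, st == p[2]]
      tt <- twoSampleT(g1, g2)
      v <- if (m %in% names(vip)) vip[[m]] else NA_real_
      sig <- !is.na(v) && v > vipMin && tt$p < alpha
      out[[length(out) + 1L]] <- data.frame(
        metabolite = m, stage = p[1], vip = v, p = tt$p,
        direction = if (mean(g1) >= mean(g2)) "up" else "down",
        significant = sig, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
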