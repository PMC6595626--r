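#' Pick the soft-threshold power by the scale-free topology criterion
#'
#' For each candidate power, builds the unsigned adjacency, computes
#' whole-network connectivities, bins `log10 k` against `log10`
#' frequency, and fits a line. Returns the smallest power whose fit
#' reaches `r2Target` with a negative slope; when none qualifies, the
#' power with the highest fit is returned with a warning.
#'
#' @param expr [StageExperiment-class] or genes x samples matrix.
#' @param candidates candidate integer powers (default 1..20).
#' @param r2Target scale-free fit target (default 0.8).
#' @param nBreaks connectivity histogram bins (default 10).
#' @return list: `beta` (chosen power) and `fitTable` (power, r2, slope,
#'   mean k).
#' @export
pickSoftThreshold <- function(expr, candidates = 1:20, r2Target = 0.8,
                              nBreaks = 10) {
  x <- exprMatrix(expr)
  if (ncol(x) < 3)
    stop(germError("need at least 3 samples", "germDataError"))
  cc <- abs(safeCor(t(x)))
  if (all(cc - diag(nrow(cc)) == 0) && nrow(cc) > 1)
    warning("expression is degenerate (no correlation structure)")
  fit <- t(vapply(candidates, function(b) {
    A <- cc^b
    k <- rowSums(A) - 1
    scaleFreeFit(k, nBreaks)
  }, numeric(3)))
  colnames(fit) <- c("r2", "slope", "meanK")
  tab <- data.frame(power = candidates, fit)
  ok <- which(tab$r2 >= r2Target & tab$slope < 0)
  if (length(ok)) beta <- tab$power[ok[1]]
  else {
    beta <- tab$power[which.max(tab$r2)]
    warning(sprintf(
      "no power reached R^2 >= %.2f; using argmax R^2 (power %d)",
      r2Target, beta))
  }
  list(beta = beta, fitTable = tab)
}

scaleFreeFit <- function(k, nBreaks) {
  k <- k[k > 0]
  if (length(unique(k)) < 2) return(c(0, 0, mean(k)))
  br <- seq(min(k), max(k), length.out = nBreaks + 1)
  cut <- findInterval(k, br, rightmost.closed = TRUE)
  freq <- tabulate(cut, nBreaks) / length(k)
  mid <- (br[-1] + br[-length(br)]) / 2
  keep <- freq > 0
  if (sum(keep) < 3) return(c(0, 0, mean(k)))
  lx <- log10(mid[keep]); ly <- log10(freq[keep])
  f <- lm(ly ~ lx)
  c(summary(f)$r.squared, coef(f)[2], mean(k))
}

#' Unsigned soft-threshold adjacency
#'
#' `a_ij = |cor(x_i, x_j)|^beta`, unit diagonal. Zero-variance genes are
#' dropped with a warning; a signed variant
#' (`((1 + cor)/2)^beta`) is available via `type = "signed"`.
#'
#' @inheritParams pickSoftThreshold
#' @param beta soft-threshold power.
#' @param type `"unsigned"` (default) or `"signed"`.
#' @return adjacency matrix with gene dimnames.
#' @export
adjacencyMatrix <- function(expr, beta, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  x <- exprMatrix(expr)
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance gene(s)", sum(sds == 0)))
    x <- x[sds > 0, , drop = FALSE]
  }
  cc <- safeCor(t(x))
  A <- if (type == "unsigned") abs(cc)^beta else ((1 + cc) / 2)^beta
  diag(A) <- 1
  A
}

exprMatrix <- function(expr) {
  if (methods::is(expr, "SummarizedExperiment"))
    SummarizedExperiment::assay(expr)
  else as.matrix(expr)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' `TOM_ii = 1`. Symmetric with values in `[0, 1]`.
#'
#' @param A adjacency matrix (unit diagonal, values in `[0,1]`).
#' @return TOM matrix with the same dimnames.
#' @export
tomSimilarity <- function(A) {
  n <- nrow(A)
  k <- rowSums(A) - 1
  # (A %*% A)_ij counts u = i and u = j (diag 1): subtract 2 a_ij
  L <- A %*% A - 2 * A
  num <- L + A
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  tom[tom < 0] <- 0   # guard tiny negative rounding
  dimnames(tom) <- dimnames(A)
  tom
}

#' Build a coexpression network object
#'
#' @inheritParams adjacencyMatrix
#' @return A [CoexpressionNetwork-class] holding adjacency and TOM.
#' @export
buildCoexpressionNetwork <- function(expr, beta,
                                     type = c("unsigned", "signed")) {
  A <- adjacencyMatrix(expr, beta, type)
  methods::new("CoexpressionNetwork", genes = rownames(A), beta = beta,
               adjacency = A, tom = tomSimilarity(A))
}

# WGCNA-style module color ordering (by decreasing module size)
moduleColorOrder <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black",
  "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue")

#' Detect modules by static cut of the 1 - TOM dendrogram
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - TOM`, cut at a fixed height; branches smaller than `minSize`
#' become `"grey"` (unassigned). Remaining modules are labeled by
#' decreasing size with the conventional color ordering (turquoise,
#' blue, brown, ...); size ties are broken by the smallest member gene
#' id, so labels do not depend on gene input order.
#'
#' @param tom TOM matrix (or a [CoexpressionNetwork-class]).
#' @param cutHeight static cut height on the 1 - TOM scale (default
#'   0.25).
#' @param minSize minimum module size (default 30).
#' @return named character vector gene -> module color.
#' @export
detectModules <- function(tom, cutHeight = 0.25, minSize = 30) {
  if (methods::is(tom, "CoexpressionNetwork")) tom <- tom@tom
  if (minSize < 2)
    stop(germError("minSize must be >= 2", "germConfigError"))
  genes <- rownames(tom)
  if (nrow(tom) < minSize)
    return(setNames(rep("grey", nrow(tom)), genes))
  hc <- hclust(as.dist(1 - tom), method = "average")
  grp <- cutree(hc, h = cutHeight)
  sizes <- table(grp)
  keep <- names(sizes)[sizes >= minSize]
  labels <- setNames(rep("grey", length(genes)), genes)
  if (length(keep)) {
    firstGene <- vapply(keep, function(g) min(genes[grp == g]),
                        character(1))
    ord <- keep[order(-sizes[keep], firstGene)]
    for (i in seq_along(ord))
      labels[grp == as.integer(ord[i])] <-
        moduleColorOrder[min(i, length(moduleColorOrder))]
  }
  labels
}

#' Module eigengene: first principal component of the module submatrix
#'
#' Genes are standardized across samples; the eigengene is the leading
#' right singular vector (unit norm, one value per sample), oriented so
#' the average gene-eigengene correlation is positive. Variance
#' explained is the leading eigenvalue's share.
#'
#' @inheritParams pickSoftThreshold
#' @param genes module member gene ids.
#' @return list: `me` (named numeric per sample), `varExplained`.
#' @export
moduleEigengene <- function(expr, genes) {
  x <- exprMatrix(expr)
  if (length(genes) == 0)
    stop(germError("empty module", "germDataError"))
  x <- x[genes, , drop = FALSE]
  sds <- apply(x, 1, sd)
  x <- x[sds > 0, , drop = FALSE]
  if (nrow(x) == 0)
    stop(germError("module has no variable genes", "germDegenerateError"))
  xs <- t(scale(t(x)))
  sv <- svd(xs)
  me <- sv$v[, 1]
  if (mean(cor(t(xs), me)) < 0) me <- -me
  list(me = setNames(me, colnames(x)),
       varExplained = sv$d[1]^2 / sum(sv$d^2))
}

#' Eigengenes for every non-grey module
#'
#' @inheritParams pickSoftThreshold
#' @param labels gene -> module labels from [detectModules()].
#' @return A [ModuleSet-class].
#' @export
moduleEigengenes <- function(expr, labels) {
  mods <- setdiff(unique(labels), "grey")
  mods <- mods[order(match(mods, moduleColorOrder))]
  x <- exprMatrix(expr)
  mes <- lapply(mods, function(m)
    moduleEigengene(x, names(labels)[labels == m]))
  eg <- do.call(rbind, lapply(mes, `[[`, "me"))
  if (is.null(eg)) eg <- matrix(numeric(0), 0, ncol(x),
                                dimnames = list(NULL, colnames(x)))
  else rownames(eg) <- mods
  methods::new("ModuleSet", labels = labels, eigengenes = eg,
               varExplained = setNames(
                 vapply(mes, `[[`, numeric(1), "varExplained"), mods))
}

#' Module-stage correlation statistics
#'
#' Pearson correlation of each eigengene with the one-hot indicator of
#' each stage over all samples; two-sided Student-t p-value with
#' `t = r sqrt(n-2) / sqrt(1-r^2)` on `n - 2` degrees of freedom
#' (n = 18 for a 6-stage x 3-replicate design).
#'
#' @param me eigengene values (one per sample), a matrix of eigengenes
#'   (modules x samples), or a [ModuleSet-class].
#' @param stage stage index per sample.
#' @return data.frame: `module`, `stage`, `r`, `p`.
#' @export
moduleStageCorrelation <- function(me, stage) {
  if (methods::is(me, "ModuleSet")) me <- me@eigengenes
  if (is.null(dim(me))) me <- matrix(me, 1,
                                     dimnames = list("ME", names(me)))
  n <- ncol(me)
  if (n < 3) stop(germError("need at least 3 samples", "germDataError"))
  if (length(stage) != n)
    stop(germError("one stage per sample required", "germDataError"))
  if (any(apply(me, 1, sd) == 0))
    stop(germError("constant eigengene", "germDegenerateError"))
  out <- list()
  for (m in seq_len(nrow(me))) for (s in sort(unique(stage))) {
    ind <- as.numeric(stage == s)
    r <- cor(me[m, ], ind)
    out[[length(out) + 1L]] <- data.frame(
      module = rownames(me)[m], stage = s, r = r,
      p = corPvalue(r, n), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# two-sided Student-t p for a Pearson correlation, df = n - 2
corPvalue <- function(r, n) {
  r <- max(-1, min(1, r))
  if (abs(r) >= 1) return(.Machine$double.xmin)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  max(2 * pt(-abs(t), n - 2), .Machine$double.xmin)
}

#' Intramodular connectivity and hub genes
#'
#' `k_within(i) = sum over module co-members of a_ij`. Hubs are the `n`
#' module genes with the highest `k_within`, ties broken by gene id.
#'
#' @param A adjacency matrix (or [CoexpressionNetwork-class]).
#' @param module module member gene ids.
#' @return named numeric `k_within`, sorted as in `module`.
#' @export
intramodularConnectivity <- function(A, module) {
  if (methods::is(A, "CoexpressionNetwork")) A <- A@adjacency
  if (!all(module %in% rownames(A)))
    stop(germError("module genes absent from network", "germDataError"))
  sub <- A[module, module, drop = FALSE]
  setNames(rowSums(sub) - diag(sub), module)
}

#' @rdname intramodularConnectivity
#' @param kWithin connectivities from `intramodularConnectivity()`.
#' @param n number of hubs (default 10).
#' @export
topHubs <- function(kWithin, n = 10) {
  ord <- order(-kWithin, names(kWithin))
  names(kWithin)[ord][seq_len(min(n, length(kWithin)))]
}

setMethod("show", "CoexpressionNetwork", function(object) {
  cat("CoexpressionNetwork:", length(object@genes), "genes, beta =",
      object@beta, "\n")
  cat("  mean connectivity:",
      signif(mean(rowSums(object@adjacency) - 1), 4), "\n")
})

setMethod("show", "ModuleSet", function(object) {
  tab <- table(object@labels)
  cat("ModuleSet:", length(object@labels), "genes,",
      sum(names(tab) != "grey"), "modules\n")
  for (m in rownames(object@eigengenes))
    cat(sprintf("  %-12s %4d genes, varExplained %.2f\n", m, tab[[m]],
                object@varExplained[[m]]))
  if ("grey" %in% names(tab))
    cat(sprintf("  %-12s %4d genes (unassigned)\n", "grey",
                tab[["grey"]]))
})

#' Export a weighted network above a threshold
#'
#' Writes edges with weight at or above `threshold` as SIF, GraphML and
#' TSV, with node attributes (module, hub flag, transcription-factor
#' flag) when supplied.
#'
#' @param mat adjacency or TOM matrix.
#' @param threshold edge weight threshold in `[0, 1]`.
#' @param dir output directory.
#' @param name file stem (default `"network"`).
#' @param nodeAttrs optional data.frame with a `gene_id` column plus
#'   attribute columns.
#' @return (invisibly) the edge data.frame.
#' @export
exportNetwork <- function(mat, threshold, dir, name = "network",
                          nodeAttrs = NULL) {
  if (threshold < 0 || threshold > 1)
    stop(germError("threshold must lie in [0,1]", "germConfigError"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ut <- upper.tri(mat)
  hit <- which(ut & mat >= threshold, arr.ind = TRUE)
  edges <- data.frame(source = rownames(mat)[hit[, 1]],
                      target = colnames(mat)[hit[, 2]],
                      weight = mat[hit], stringsAsFactors = FALSE)
  utils::write.table(edges, file.path(dir, paste0(name, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("%s\tco\t%s", edges$source, edges$target),
             file.path(dir, paste0(name, ".sif")))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = if (is.null(nodeAttrs))
      data.frame(name = rownames(mat)) else
      cbind(data.frame(name = nodeAttrs$gene_id),
            nodeAttrs[setdiff(colnames(nodeAttrs), "gene_id")]))
  igraph::write_graph(g, file.path(dir, paste0(name, ".graphml")),
                      format = "graphml")
  invisible(edges)
}
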