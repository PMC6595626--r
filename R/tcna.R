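# permutation matrices cached per n (n <= 8 -> at most 40320 x 8)
.permCache <- new.env(parent = emptyenv())

allPermutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.permCache[[key]])) return(.permCache[[key]])
  rec <- function(m) {
    if (m == 1L) return(matrix(1L))
    p <- rec(m - 1L)
    do.call(rbind, lapply(seq_len(m), function(i)
      cbind(i, p + (p >= i))))
  }
  out <- rec(n)
  .permCache[[key]] <- out
  out
}

#' Spearman correlation with an exact permutation p-value
#'
#' `rho` is the Pearson correlation of (average-tied) ranks. For
#' `n <= exactNMax` the two-sided p-value is computed by full
#' enumeration of all `n!` rank permutations:
#' `p = #\{perm: |rho_perm| >= |rho_obs|\} / n!` — at n = 6 this is 720
#' permutations, where the t-approximation is unreliable. For larger n
#' the Student-t approximation on `n - 2` degrees of freedom is used.
#' A constant input vector has undefined rank correlation; `rho = 0`,
#' `p = 1` is returned with `degenerate = TRUE`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exactNMax largest n for exact enumeration (default 8).
#' @return list: `rho`, `p`, `degenerate`.
#' @examples
#' spearmanExact(1:6, c(2, 3, 5, 8, 13, 21))  # rho = 1, p = 2/720
#' @export
spearmanExact <- function(x, y, exactNMax = 8) {
  n <- length(x)
  if (n != length(y) || n < 3)
    stop(germError("need equal-length vectors of length >= 3",
                   "germDataError"))
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = 0, p = 1, degenerate = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= exactNMax) {
    P <- allPermutations(n)
    zx <- (rx - mean(rx)) / sd(rx)
    zy <- (ry - mean(ry)) / sd(ry)
    # rho under each permutation of y's ranks against fixed x ranks
    rhos <- as.numeric(matrix(zy[P], nrow(P)) %*% zx) / (n - 1)
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    p <- corPvalue(rho, n)
  }
  list(rho = rho, p = p, degenerate = FALSE)
}

#' Build a targeted correlation network (TCNA)
#'
#' For each target metabolite, correlates the 6-point stage-mean
#' trajectories of its annotated enzyme-family members (synthesis /
#' decomposition roles) with the metabolite's trajectory, and adds a
#' metabolite-metabolite backbone edge for every pathway-adjacent pair.
#' Each edge carries the exact-permutation Spearman `(rho, p)`, a
#' significance flag (`p <= alpha` AND `|rho| >= rMin`; solid vs dashed
#' in a Cytoscape rendering) and the correlation sign. All computed
#' family edges are kept so every member can be ranked; `retained`
#' marks edges passing the `|rho| >= rMin` display filter.
#'
#' @param exprProfiles genes x 6 stage-mean matrix (see
#'   [stageMeans()]).
#' @param metabProfiles metabolites x 6 stage-mean matrix.
#' @param enzymeMap data.frame: `gene_id`, `metabolite_id`, `role`
#'   (`"synthesis"` or `"decomposition"`).
#' @param pathwayEdges data.frame: `metabolite_a`, `metabolite_b`
#'   (may be empty or `NULL`).
#' @param rMin display correlation threshold (default 0.25).
#' @param alpha significance level (default 0.05).
#' @param targets target metabolites (default: all in `enzymeMap`).
#' @return A [TCNAGraph-class].
#' @export
buildTCNA <- function(exprProfiles, metabProfiles, enzymeMap,
                      pathwayEdges = NULL, rMin = 0.25, alpha = 0.05,
                      targets = NULL) {
  if (is.null(targets)) targets <- sort(unique(enzymeMap$metabolite_id))
  absent <- setdiff(targets, rownames(metabProfiles))
  if (length(absent))
    stop(germError(sprintf("target metabolite(s) absent: %s",
                           paste(absent, collapse = ", ")),
                   "germDataError"))
  edges <- list()
  addEdge <- function(src, tgt, type, role, sp) {
    edges[[length(edges) + 1L]] <<- data.frame(
      source = src, target = tgt, type = type, role = role,
      rho = sp$rho, p = sp$p,
      significant = sp$p <= alpha && abs(sp$rho) >= rMin,
      sign = if (sp$rho >= 0) "positive" else "negative",
      retained = abs(sp$rho) >= rMin, stringsAsFactors = FALSE)
  }
  usedGenes <- character(0)
  for (m in targets) {
    fam <- enzymeMap[enzymeMap$metabolite_id == m, , drop = FALSE]
    fam <- fam[order(fam$gene_id), , drop = FALSE]
    fam <- fam[!duplicated(fam$gene_id), , drop = FALSE]
    if (nrow(fam) == 0) {
      warning(sprintf("no annotated family members for %s; skipped", m))
      next
    }
    for (i in seq_len(nrow(fam))) {
      g <- fam$gene_id[i]
      if (!g %in% rownames(exprProfiles))
        stop(germError(sprintf("gene %s missing from profiles", g),
                       "germDataError"))
      sp <- spearmanExact(exprProfiles[g, ], metabProfiles[m, ])
      addEdge(g, m, "gene-metabolite", fam$role[i], sp)
      usedGenes <- c(usedGenes, g)
    }
  }
  if (!is.null(pathwayEdges) && nrow(pathwayEdges)) {
    pe <- pathwayEdges[order(pathwayEdges$metabolite_a,
                             pathwayEdges$metabolite_b), , drop = FALSE]
    for (i in seq_len(nrow(pe))) {
      a <- pe$metabolite_a[i]; b <- pe$metabolite_b[i]
      if (!all(c(a, b) %in% rownames(metabProfiles)))
        stop(germError("pathway edge references unknown metabolite",
                       "germDataError"))
      sp <- spearmanExact(metabProfiles[a, ], metabProfiles[b, ])
      addEdge(a, b, "metabolite-metabolite", "pathway-adjacent", sp)
    }
  }
  e <- if (length(edges)) do.call(rbind, edges) else
    data.frame(source = character(0), target = character(0),
               type = character(0), role = character(0),
               rho = numeric(0), p = numeric(0),
               significant = logical(0), sign = character(0),
               retained = logical(0))
  mets <- unique(c(targets,
                   e$source[e$type == "metabolite-metabolite"],
                   e$target[e$type == "metabolite-metabolite"]))
  nodes <- rbind(
    data.frame(id = sort(unique(usedGenes)), type = "gene",
               stringsAsFactors = FALSE),
    data.frame(id = sort(mets), type = "metabolite",
               stringsAsFactors = FALSE))
  methods::new("TCNAGraph", nodes = nodes, edges = e, rMin = rMin,
               alpha = alpha)
}

#' Rank enzyme-family members for a target metabolite
#'
#' Family members sorted by `|rho|` descending, ties by smaller p, then
#' lexicographic gene id; the top-ranked gene is the candidate driver of
#' the metabolite's trajectory.
#'
#' @param graph a [TCNAGraph-class].
#' @param metabolite target metabolite id.
#' @return data.frame: `metabolite`, `rank`, `gene_id`, `rho`, `p`.
#' @export
rankCandidates <- function(graph, metabolite) {
  e <- graph@edges
  e <- e[e$type == "gene-metabolite" & e$target == metabolite, ,
         drop = FALSE]
  if (nrow(e) == 0)
    stop(germError(sprintf("no gene edges for %s", metabolite),
                   "germDataError"))
  ord <- order(-abs(e$rho), e$p, e$source)
  data.frame(metabolite = metabolite, rank = seq_len(nrow(e)),
             gene_id = e$source[ord], rho = e$rho[ord], p = e$p[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

setMethod("show", "TCNAGraph", function(object) {
  e <- object@edges
  cat("TCNAGraph:", nrow(object@nodes), "nodes,", nrow(e), "edges\n")
  cat(sprintf("  %d gene-metabolite, %d backbone; %d significant (p <= %g, |rho| >= %g)\n",
              sum(e$type == "gene-metabolite"),
              sum(e$type == "metabolite-metabolite"),
              sum(e$significant), object@alpha, object@rMin))
})

#' Export a TCNA graph for Cytoscape
#'
#' Writes `tcna_edges.tsv` (all edges), `tcna.sif` and `tcna.graphml`
#' (retained edges, i.e. `|rho| >= rMin`), and `candidate_genes.tsv`
#' (per-metabolite rankings). GraphML nodes carry
#' `shape = triangle` (gene) / `rectangle` (metabolite); edges carry
#' `style = solid/dashed`, `color = red/blue` (positive/negative),
#' `rho` and `p`.
#'
#' @param graph a [TCNAGraph-class].
#' @param dir output directory.
#' @return (invisibly) the written file paths.
#' @export
exportTCNA <- function(graph, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  e <- graph@edges
  utils::write.table(e, file.path(dir, "tcna_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  er <- e[e$retained, , drop = FALSE]
  writeLines(sprintf("%s\t%s\t%s", er$source,
                     ifelse(er$type == "gene-metabolite", "gm", "mm"),
                     er$target),
             file.path(dir, "tcna.sif"))
  nodes <- graph@nodes
  nodes$shape <- ifelse(nodes$type == "gene", "triangle", "rectangle")
  used <- unique(c(er$source, er$target))
  g <- igraph::graph_from_data_frame(
    data.frame(from = er$source, to = er$target, rho = er$rho,
               p = er$p,
               style = ifelse(er$significant, "solid", "dashed"),
               color = ifelse(er$sign == "positive", "red", "blue"),
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = nodes[nodes$id %in% used | nrow(er) == 0,
                     c("id", "type", "shape")])
  igraph::write_graph(g, file.path(dir, "tcna.graphml"),
                      format = "graphml")
  ranks <- lapply(sort(unique(
    e$target[e$type == "gene-metabolite"])),
    function(m) rankCandidates(graph, m))
  if (length(ranks))
    utils::write.table(do.call(rbind, ranks),
                       file.path(dir, "candidate_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, c("tcna_edges.tsv", "tcna.sif",
                             "tcna.graphml", "candidate_genes.tsv")))
}
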