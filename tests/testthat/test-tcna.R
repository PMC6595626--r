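test_that("stage means average replicates on the original scale", {
  m <- matrix(c(1, 3, 10, 20,
                5, 5, 5, 5), 2, 4, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  sm <- stageMeans(m, stage = c(1, 1, 2, 2))
  expect_equal(sm["a", ], c(`1` = 2, `2` = 15))
  expect_equal(sm["b", ], c(`1` = 5, `2` = 5))
  # single replicate per stage: identity
  one <- matrix(1:6, 1, dimnames = list("x", NULL))
  expect_equal(unname(stageMeans(one, stage = 1:6)["x", ]), 1:6)
})

test_that("exact Spearman p-values agree with full enumeration", {
  sp <- spearmanExact(1:6, c(2, 3, 5, 8, 13, 21))
  expect_equal(sp$rho, 1)
  expect_equal(sp$p, 2 / 720)
  rev <- spearmanExact(1:6, -c(2, 3, 5, 8, 13, 21))
  expect_equal(rev$rho, -1)
  expect_equal(rev$p, 2 / 720)
  set.seed(19)
  for (n in c(5, 6, 7)) for (i in 1:5) {
    x <- rnorm(n); y <- rnorm(n)
    sp <- spearmanExact(x, y)
    oc <- oracleSpearman(x, y)
    expect_equal(sp$rho, oc$rho)
    expect_equal(sp$p, oc$p)
    # independent reference: R's exact Spearman test (no ties)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(sp$rho, unname(ct$estimate))
  }
  # beyond exactNMax the t-approximation takes over
  x <- rnorm(12); y <- rnorm(12)
  sp <- spearmanExact(x, y, exactNMax = 8)
  r <- cor(rank(x), rank(y))
  expect_equal(sp$p, 2 * pt(-abs(r * sqrt(10) / sqrt(1 - r^2)), 10),
               tolerance = 1e-12)
  # constant vector: degenerate, rho 0, p 1
  dg <- spearmanExact(rep(1, 6), rnorm(6))
  expect_true(dg$degenerate)
  expect_equal(c(dg$rho, dg$p), c(0, 1))
  # invariant under strictly monotone transforms
  x <- rnorm(6); y <- rnorm(6)
  a <- spearmanExact(x, y)
  b <- spearmanExact(exp(x), rank(y)^3)
  expect_equal(a[c("rho", "p")], b[c("rho", "p")])
})

test_that("at n = 6 significance requires |rho| above 0.77", {
  # exact null: the smallest |rho| whose two-sided p is <= 0.05
  rhos <- apply(oraclePerms(6), 1, function(p) cor(1:6, p))
  pOf <- function(r) mean(abs(rhos) >= r - 1e-12)
  crit <- min(abs(rhos)[vapply(abs(rhos), pOf, numeric(1)) <= 0.05])
  expect_gte(crit, 0.77)
  # hence every significant TCNA edge clears any r_min <= 0.77
  expect_true(pOf(29 / 35) > 0.05)  # 0.829 is not enough two-sided
})

test_that("TCNA graph links families, backbones, and ranks candidates", {
  d <- generateDataset(simConfig(nGenes = 300, nMetabolites = 6,
                                 noiseSd = 0, causalGeneRho = 1,
                                 seed = 23))
  g <- buildTCNA(stageMeans(d$expression), stageMeans(d$metabolites),
                 d$enzymeMap, d$pathwayEdges)
  e <- g@edges
  # causal edges: rho = 1, significant (p = 2/720)
  for (m in names(d$truth$causalGene)) {
    ce <- e[e$source == d$truth$causalGene[[m]] & e$target == m, ]
    expect_equal(ce$rho, 1)
    expect_equal(ce$p, 2 / 720)
    expect_true(ce$significant)
    top <- rankCandidates(g, m)
    expect_equal(top$gene_id[1], d$truth$causalGene[[m]])
  }
  # pathway-adjacent metabolites form positive backbone edges
  bb <- e[e$type == "metabolite-metabolite", ]
  expect_equal(nrow(bb), nrow(d$pathwayEdges))
  expect_true(all(bb$sign == "positive"))
  # order invariance: shuffled inputs give the same edge table
  set.seed(1)
  em2 <- d$enzymeMap[sample(nrow(d$enzymeMap)), ]
  g2 <- buildTCNA(stageMeans(d$expression), stageMeans(d$metabolites),
                  em2, d$pathwayEdges)
  expect_equal(g2@edges, e)
  expect_error(buildTCNA(stageMeans(d$expression),
                         stageMeans(d$metabolites), d$enzymeMap,
                         targets = "missing_met"),
               class = "germDataError")
})

test_that("non-significant edges above rMin stay in the graph as dashed", {
  # |rho| = 0.6 at n = 6: retained but p > 0.05, so not significant
  ex <- matrix(c(1, 2, 3, 6, 4, 5), 1, dimnames = list("gA", NULL))
  mx <- matrix(c(1, 2, 4, 3, 6, 5), 1, dimnames = list("mA", NULL))
  emap <- data.frame(gene_id = "gA", metabolite_id = "mA",
                     role = "synthesis")
  g <- buildTCNA(ex, mx, emap)
  e <- g@edges
  expect_gte(abs(e$rho), 0.25)
  expect_gt(e$p, 0.05)
  expect_false(e$significant)
  expect_true(e$retained)
})

test_that("candidate ranking breaks ties by p then gene id", {
  edges <- data.frame(
    source = c("g3", "g1", "g2", "g4"), target = "met",
    type = "gene-metabolite", role = "synthesis",
    rho = c(0.9, 0.5, -0.5, 0.1), p = c(0.01, 0.20, 0.03, 0.9),
    significant = c(TRUE, FALSE, FALSE, FALSE),
    sign = c("positive", "positive", "negative", "positive"),
    retained = c(TRUE, TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  g <- methods::new("TCNAGraph",
                    nodes = data.frame(id = c(paste0("g", 1:4), "met"),
                                       type = c(rep("gene", 4),
                                                "metabolite")),
                    edges = edges, rMin = 0.25, alpha = 0.05)
  rk <- rankCandidates(g, "met")
  expect_equal(rk$gene_id, c("g3", "g2", "g1", "g4"))
  expect_error(rankCandidates(g, "other"), class = "germDataError")
})

test_that("TCNA exports round-trip and count edges correctly", {
  d <- generateDataset(simConfig(nGenes = 300, nMetabolites = 6,
                                 seed = 25))
  g <- buildTCNA(stageMeans(d$expression), stageMeans(d$metabolites),
                 d$enzymeMap, d$pathwayEdges)
  dir <- withr::local_tempdir()
  exportTCNA(g, dir)
  er <- g@edges[g@edges$retained, ]
  expect_equal(length(readLines(file.path(dir, "tcna.sif"))), nrow(er))
  gg <- igraph::read_graph(file.path(dir, "tcna.graphml"),
                           format = "graphml")
  el <- igraph::as_data_frame(gg)
  expect_setequal(paste(el$from, el$to), paste(er$source, er$target))
  ord <- match(paste(er$source, er$target), paste(el$from, el$to))
  expect_equal(el$rho[ord], er$rho)
  expect_equal(el$style[ord], ifelse(er$significant, "solid", "dashed"))
  vt <- igraph::as_data_frame(gg, "vertices")
  expect_true(all(vt$shape[vt$type == "gene"] == "triangle"))
  # empty graph still writes valid files
  g0 <- methods::new("TCNAGraph",
                     nodes = data.frame(id = character(0),
                                        type = character(0)),
                     edges = g@edges[0, ], rMin = 0.25, alpha = 0.05)
  d2 <- withr::local_tempdir()
  exportTCNA(g0, d2)
  expect_equal(length(readLines(file.path(d2, "tcna.sif"))), 0)
  expect_s3_class(igraph::as_data_frame(
    igraph::read_graph(file.path(d2, "tcna.graphml"),
                       format = "graphml")), "data.frame")
})
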