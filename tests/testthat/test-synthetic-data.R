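test_that("identical configs give identical datasets", {
  cfg <- simConfig(nGenes = 300, nMetabolites = 6, seed = 42)
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_identical(SummarizedExperiment::assay(d1$expression),
                   SummarizedExperiment::assay(d2$expression))
  expect_identical(SummarizedExperiment::assay(d1$metabolites),
                   SummarizedExperiment::assay(d2$metabolites))
  expect_identical(d1$annotation, d2$annotation)
  expect_identical(d1$enzymeMap, d2$enzymeMap)
  expect_identical(d1$truth, d2$truth)
  d3 <- generateDataset(simConfig(nGenes = 300, nMetabolites = 6,
                                  seed = 43))
  expect_false(identical(SummarizedExperiment::assay(d1$expression),
                         SummarizedExperiment::assay(d3$expression)))
})

test_that("dataset has the six-stage design and planted structure", {
  cfg <- simConfig(nGenes = 300, nMetabolites = 6, seed = 7)
  d <- generateDataset(cfg)
  expect_equal(dim(d$expression), c(300L, 18L))
  expect_equal(dim(d$metabolites), c(6L, 36L))
  expect_equal(as.integer(table(stages(d$expression))), rep(3L, 6))
  expect_equal(as.integer(table(stages(d$metabolites))), rep(6L, 6))
  expect_true(all(SummarizedExperiment::assay(d$expression) > 0))
  expect_true(all(SummarizedExperiment::assay(d$metabolites) > 0))
  # every causal gene is annotated to its metabolite in the enzyme map
  for (m in names(d$truth$causalGene)) {
    fam <- d$enzymeMap[d$enzymeMap$metabolite_id == m, ]
    expect_true(d$truth$causalGene[[m]] %in% fam$gene_id)
    expect_true(all(fam$role %in% c("synthesis", "decomposition")))
  }
  # planted modules are at least the default minimum module size
  expect_true(all(table(unlist(d$truth$moduleOf)) >= 30))
  expect_error(simConfig(exprReplicates = 1), class = "germConfigError")
  expect_error(simConfig(nGenes = 10), class = "germConfigError")
})

test_that("noiseless planted structure is exact", {
  d <- generateDataset(simConfig(nGenes = 300, nMetabolites = 6,
                                 noiseSd = 0, causalGeneRho = 1,
                                 seed = 3))
  em <- stageMeans(d$expression)
  mm <- stageMeans(d$metabolites)
  # causal coupling: Spearman rho exactly 1 on stage means
  for (m in names(d$truth$causalGene)) {
    g <- d$truth$causalGene[[m]]
    expect_equal(cor(rank(em[g, ]), rank(mm[m, ])), 1)
  }
  # cluster genes peak exactly at their planted stage
  peaks <- unlist(d$truth$clusterPeakStage)
  for (g in names(d$truth$clusterOf)) {
    cl <- d$truth$clusterOf[[g]]
    expect_equal(which.max(em[g, ]), peaks[[cl]], ignore_attr = TRUE)
  }
  # single-stage TFs pass tau = 1 FPKM in exactly their planted stage
  ssg <- singleStageGenes(d$expression, tau = 1)
  tf <- unlist(d$truth$singleStageTF)
  expect_true(all(names(tf) %in% names(ssg)))
  expect_equal(ssg[names(tf)], tf)
})

test_that("imbibition series is piecewise linear and validated", {
  s <- generateImbibitionSeries(breakpoints = c(120, 600),
                                slopes = c(0.004, 0.001, 0.003),
                                noiseSd = 0, seed = 1, w0 = 1)
  expect_equal(s$weight_g[s$time_min == 120], 1 + 0.48)
  expect_equal(s$weight_g[s$time_min == 600], 1 + 0.48 + 0.48)
  # exactly piecewise linear: second differences vanish within segments
  seg1 <- s$weight_g[s$time_min < 120]
  expect_true(all(abs(diff(diff(seg1))) < 1e-12))
  expect_error(generateImbibitionSeries(breakpoints = c(600, 120)),
               class = "germConfigError")
  expect_error(
    generateImbibitionSeries(slopes = c(0.001, 0.004, 0.003)),
    class = "germConfigError")
})

test_that("write/read round-trips the dataset exactly", {
  d <- generateDataset(simConfig(nGenes = 300, nMetabolites = 6,
                                 seed = 5))
  dir <- withr::local_tempdir()
  manifest <- writeGerminationDataset(d, dir)
  expect_setequal(names(manifest$files),
                  c("expression.tsv", "metabolites.tsv",
                    "annotation.tsv", "enzyme_map.tsv",
                    "pathway_edges.tsv", "truth.json"))
  expect_equal(manifest$files$expression.tsv$rows, 300)
  expect_equal(manifest$files$expression.tsv$cols, 18)
  expect_equal(manifest$seed, 5)
  r <- readGerminationDataset(dir)
  expect_identical(SummarizedExperiment::assay(r$expression),
                   SummarizedExperiment::assay(d$expression))
  expect_identical(SummarizedExperiment::assay(r$metabolites),
                   SummarizedExperiment::assay(d$metabolites))
  expect_equal(r$annotation, d$annotation)
  expect_equal(normalizeTruth(r$truth), normalizeTruth(d$truth))
})
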