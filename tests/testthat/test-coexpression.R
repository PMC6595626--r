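test_that("adjacency is |cor|^beta with unit diagonal", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),
             c = c(1, -1, 1, -1))
  A <- adjacencyMatrix(x, beta = 6)
  expect_equal(A["a", "b"], 1)
  expect_equal(diag(A), rep(1, 3), ignore_attr = TRUE)
  # cor exactly -0.5 at beta 2 -> 0.25
  y <- rbind(p = c(1, 0, -1), q = c(-1, 1, 0))
  expect_equal(cor(y["p", ], y["q", ]), -0.5)
  expect_equal(adjacencyMatrix(y, 2)["p", "q"], 0.25)
  # orthogonal profiles -> 0
  z <- rbind(u = c(1, -1, 1, -1), v = c(1, 1, -1, -1))
  expect_equal(adjacencyMatrix(z, 6)["u", "v"], 0)
  expect_warning(adjacencyMatrix(rbind(a = 1:4, b = rep(2, 4)), 6),
                 "zero-variance")
})

test_that("TOM matches its defining formula", {
  A <- diag(3)
  A[1, 2] <- A[2, 1] <- 0.8
  A[1, 3] <- A[3, 1] <- 0.4
  A[2, 3] <- A[3, 2] <- 0.2
  tom <- tomSimilarity(A)
  expect_equal(tom[1, 2], 0.88 / 1.2)
  expect_equal(tom, t(tom))
  expect_equal(diag(tom), rep(1, 3), ignore_attr = TRUE)
  # no edges -> no overlap
  expect_equal(tomSimilarity(diag(4)) - diag(4), matrix(0, 4, 4))
  # triple-loop oracle on random adjacencies
  set.seed(8)
  for (rep in 1:3) {
    M <- matrix(runif(100), 10)
    A <- (M + t(M)) / 2
    diag(A) <- 1
    tom <- tomSimilarity(A)
    expect_equal(max(abs(tom - oracleTOM(A))), 0, tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
})

test_that("soft threshold is selected by the scale-free criterion", {
  # hub-latent construction: gene i loads on a shared latent with
  # weight ~ i^(-1/6), so connectivity at beta = 6 follows a Zipf law
  set.seed(12)
  ns <- 18; n <- 60
  u <- 0.99 * (1:n)^(-1 / 6)
  lat <- rnorm(ns)
  x <- t(vapply(1:n, function(i)
    u[i] * lat + sqrt(1 - u[i]^2) * rnorm(ns), numeric(ns)))
  rownames(x) <- sprintf("g%03d", 1:n)
  pk <- pickSoftThreshold(x)
  expect_lte(pk$beta, 8)
  expect_gte(pk$fitTable$r2[pk$fitTable$power == pk$beta], 0.8)
  expect_identical(pickSoftThreshold(x)$beta, pk$beta)  # deterministic
  # two genes only: fallback path with warning
  expect_warning(p2 <- pickSoftThreshold(x[1:2, ]), "argmax")
  expect_true(p2$beta %in% 1:20)
})

test_that("static cut recovers planted blocks and greys the rest", {
  set.seed(13)
  ns <- 18
  # within-block correlation ~0.9 (blend weight sqrt(0.9)), across ~0
  mkblock <- function(n, lat) t(vapply(seq_len(n), function(i)
    sqrt(0.9) * lat + sqrt(0.1) * rnorm(ns), numeric(ns)))
  x <- rbind(mkblock(40, rnorm(ns)), mkblock(35, rnorm(ns)))
  rownames(x) <- sprintf("g%03d", 1:75)
  net <- buildCoexpressionNetwork(x, beta = 2)
  labels <- detectModules(net, minSize = 30)
  expect_equal(sort(unique(labels)), c("blue", "turquoise"))
  expect_equal(length(unique(labels[1:40])), 1)   # block 1 intact
  expect_equal(length(unique(labels[41:75])), 1)  # block 2 intact
  expect_equal(unname(labels[1]), "turquoise")    # larger block first
  # permutation invariance of the induced partition
  perm <- sample(75)
  labp <- detectModules(buildCoexpressionNetwork(x[perm, ], 2),
                        minSize = 30)
  expect_equal(labp[rownames(x)], labels)
  # unstructured genes: all grey
  noise <- matrix(rnorm(10 * ns), 10,
                  dimnames = list(sprintf("n%02d", 1:10), NULL))
  expect_true(all(detectModules(buildCoexpressionNetwork(noise, 6),
                                minSize = 5) == "grey"))
  expect_true(all(detectModules(net, minSize = 100) == "grey"))
  expect_error(detectModules(net, minSize = 1),
               class = "germConfigError")
})

test_that("eigengene is the oriented first principal component", {
  set.seed(14)
  x <- matrix(rnorm(20 * 18), 20,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  me <- moduleEigengene(x, rownames(x))
  expect_equal(sum(me$me^2), 1)
  expect_gt(abs(cor(me$me, oraclePC1(x))), 0.999)
  # no random unit direction explains more variance
  xs <- t(scale(t(x)))
  evar <- function(v) sum((xs %*% v)^2)
  best <- evar(me$me)
  rand <- replicate(100, {
    v <- rnorm(18); evar(v / sqrt(sum(v^2)))
  })
  expect_true(all(rand <= best + 1e-8))
  # identical genes: variance explained 1, ME tracks the shared profile
  sh <- matrix(rep(rnorm(18), 5), 5, byrow = TRUE,
               dimnames = list(letters[1:5], NULL))
  mi <- moduleEigengene(sh, letters[1:5])
  expect_equal(mi$varExplained, 1)
  expect_gt(cor(mi$me, sh[1, ]), 0.999999)
  # sign flip of every profile leaves the oriented ME unchanged
  mf <- moduleEigengene(-x, rownames(x))
  expect_equal(abs(cor(mf$me, me$me)), 1, tolerance = 1e-8)
  expect_error(moduleEigengene(x, character(0)),
               class = "germDataError")
})

test_that("module-stage correlation reproduces the t-test arithmetic", {
  stage <- rep(1:6, each = 3)
  set.seed(15)
  me <- rnorm(18)
  stats <- moduleStageCorrelation(me, stage)
  expect_equal(nrow(stats), 6)
  for (i in seq_len(6)) {
    ct <- cor.test(me, as.numeric(stage == stats$stage[i]))
    expect_equal(stats$r[i], unname(ct$estimate))
    expect_equal(stats$p[i], ct$p.value, tolerance = 1e-12)
  }
  # r = 0 -> p = 1 (orthogonal indicator)
  me0 <- rep(c(-1, 0, 1), 6)
  s0 <- moduleStageCorrelation(me0, stage)
  expect_equal(s0$r, rep(0, 6), tolerance = 1e-12)
  expect_equal(s0$p, rep(1, 6), tolerance = 1e-12)
  expect_error(moduleStageCorrelation(rep(1, 18), stage),
               class = "germDegenerateError")
})

test_that("intramodular connectivity and hub ordering", {
  A <- diag(3)
  A[1, 2] <- A[2, 1] <- 0.8
  A[1, 3] <- A[3, 1] <- 0.4
  A[2, 3] <- A[3, 2] <- 0.2
  dimnames(A) <- list(c("g1", "g2", "g3"), c("g1", "g2", "g3"))
  kw <- intramodularConnectivity(A, c("g1", "g2", "g3"))
  expect_equal(unname(kw), c(1.2, 1.0, 0.6))
  expect_equal(topHubs(kw, 1), "g1")
  expect_equal(intramodularConnectivity(A, "g2"), c(g2 = 0))
  # uniform adjacency: ties broken by gene id
  U <- matrix(0.5, 4, 4, dimnames = list(paste0("g", 4:1),
                                         paste0("g", 4:1)))
  diag(U) <- 1
  expect_equal(topHubs(intramodularConnectivity(U, paste0("g", 4:1)), 2),
               c("g1", "g2"))
})

test_that("network export round-trips through GraphML", {
  A <- diag(4)
  A[1, 2] <- A[2, 1] <- 0.9
  A[3, 4] <- A[4, 3] <- 0.6
  A[1, 3] <- A[3, 1] <- 1.0
  dimnames(A) <- list(paste0("g", 1:4), paste0("g", 1:4))
  dir <- withr::local_tempdir()
  edges <- exportNetwork(A, threshold = 0.5, dir = dir, name = "net")
  expect_equal(nrow(edges), 3)
  g <- igraph::read_graph(file.path(dir, "net.graphml"),
                          format = "graphml")
  el <- igraph::as_data_frame(g)
  expect_setequal(paste(el$from, el$to),
                  paste(edges$source, edges$target))
  expect_equal(sort(el$weight), sort(edges$weight))
  expect_equal(length(readLines(file.path(dir, "net.sif"))), 3)
  # threshold 1 keeps only perfect edges; threshold 0 keeps all pairs
  expect_equal(nrow(exportNetwork(A, 1, dir)), 1)
  expect_equal(nrow(exportNetwork(A, 0, dir)), choose(4, 2))
  expect_error(exportNetwork(A, 1.5, dir), class = "germConfigError")
})
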