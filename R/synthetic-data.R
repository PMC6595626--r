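#' Simulation configuration for the six-stage germination design
#'
#' Bundles and validates the parameters of [generateDataset()]. Defaults
#' describe a desk-scale study with the structure of a six-stage seed
#' germination experiment: stage-peaked expression clusters, coexpression
#' modules whose eigengenes track one stage at a controllable correlation,
#' category-enriched gene sets, single-stage transcription factors, and
#' metabolite trajectories driven by one causal member per enzyme family.
#'
#' @param nGenes,nMetabolites numbers of features.
#' @param nClustersPlanted number of stage-peaked expression clusters.
#' @param nModulesPlanted number of planted coexpression modules.
#' @param moduleStageR target Pearson correlation between each planted
#'   module's latent eigengene and the one-hot indicator of its target
#'   stage, over all expression samples (held exactly in-sample by
#'   construction).
#' @param noiseSd multiplicative log2-scale noise s.d. applied per sample.
#' @param nBins number of annotation categories.
#' @param enrichmentFold planted over-representation of one bin inside
#'   planted cluster 1.
#' @param causalGeneRho target Spearman correlation between each
#'   metabolite's stage trajectory and its causal enzyme-family member's
#'   trajectory (see Details).
#' @param seed integer master seed; one child seed per table is derived
#'   from it so, e.g., adding genes does not perturb metabolite draws.
#' @param exprReplicates,metabReplicates replicates per stage (3 and 6 by
#'   default, matching the assumed design).
#' @param nDecoys non-causal members per enzyme family.
#' @param moduleSize genes per planted module.
#' @param nSingleStageTF number of single-stage transcription factors.
#'
#' @details `causalGeneRho` is a *Spearman* target. The generator couples
#' the causal gene to the metabolite trajectory by a Pearson blend in
#' latent space whose weight is obtained by inverting the finite-n
#' bivariate-normal rank-correlation expectation
#' \deqn{E[\rho_s] = \frac{6}{\pi(n+1)}\left(\arcsin r + (n-2)\arcsin
#'   \frac{r}{2}\right)} at n = 6 stages, so that the expected Spearman
#' coupling matches the requested value.
#' @return list of class `"SimConfig"`.
#' @export
simConfig <- function(nGenes = 500, nMetabolites = 20,
                      nClustersPlanted = 6, nModulesPlanted = 3,
                      moduleStageR = 0.9, noiseSd = 0.2, nBins = 10,
                      enrichmentFold = 4, causalGeneRho = 0.9, seed = 1,
                      exprReplicates = 3, metabReplicates = 6,
                      nDecoys = 4, moduleSize = 40, nSingleStageTF = 12) {
  cfg <- list(nGenes = nGenes, nMetabolites = nMetabolites,
              nClustersPlanted = nClustersPlanted,
              nModulesPlanted = nModulesPlanted,
              moduleStageR = moduleStageR, noiseSd = noiseSd,
              nBins = nBins, enrichmentFold = enrichmentFold,
              causalGeneRho = causalGeneRho, seed = seed,
              exprReplicates = exprReplicates,
              metabReplicates = metabReplicates, nDecoys = nDecoys,
              moduleSize = moduleSize, nSingleStageTF = nSingleStageTF)
  counts <- cfg[c("nGenes", "nMetabolites", "nClustersPlanted",
                  "nModulesPlanted", "nBins", "moduleSize")]
  if (any(vapply(counts, function(x) x < 1 || x != round(x), logical(1))))
    stop(germError("all counts must be positive integers",
                   "germConfigError"))
  if (cfg$exprReplicates < 2 || cfg$metabReplicates < 2)
    stop(germError("replicate count < 2 is an invalid design",
                   "germConfigError"))
  if (moduleStageR < 0 || moduleStageR > 1 ||
      causalGeneRho < 0 || causalGeneRho > 1)
    stop(germError("moduleStageR and causalGeneRho must lie in [0,1]",
                   "germConfigError"))
  if (noiseSd < 0)
    stop(germError("noiseSd must be >= 0", "germConfigError"))
  if (enrichmentFold < 1)
    stop(germError("enrichmentFold must be >= 1", "germConfigError"))
  planted <- nModulesPlanted * moduleSize +
    nMetabolites * (1 + nDecoys) + nSingleStageTF + nClustersPlanted
  if (nGenes < planted)
    stop(germError(sprintf(
      "nGenes = %d too small for the planted structure (need >= %d)",
      nGenes, planted), "germConfigError"))
  class(cfg) <- "SimConfig"
  cfg
}

# invert E[rho_s] = 6/(pi(n+1)) (asin(w) + (n-2) asin(w/2)) for w
rhoSpearmanToPearson <- function(rho, n = 6) {
  if (rho >= 1) return(1)
  if (rho <= 0) return(0)
  f <- function(w) 6 / (pi * (n + 1)) *
    (asin(w) + (n - 2) * asin(w / 2)) - rho
  if (f(1) < 0) return(1)  # target above the attainable expectation
  uniroot(f, c(0, 1), tol = 1e-10)$root
}

# random smooth stage response over stages 1..6 (standardized)
smoothTrajectory <- function() {
  s <- 1:6
  ctr <- runif(1, 1, 6)
  wid <- runif(1, 0.8, 2)
  tr <- exp(-(s - ctr)^2 / (2 * wid^2)) +
    rnorm(1, 0, 0.2) * (s - 3.5) / 2.5
  as.numeric(scale(tr))
}

# blend a unit-variance vector with orthogonalized noise at exact
# in-sample Pearson correlation w
blendLatent <- function(z, w) {
  if (w >= 1) return(z)
  e <- rnorm(length(z))
  e <- e - z * sum(e * z) / sum(z * z)
  e <- as.numeric(scale(e))
  w * z + sqrt(1 - w^2) * e
}

binNames <- function(nBins) {
  base <- c("cell wall", "signalling", "protein synthesis",
            "protein degradation", "RNA regulation of transcription",
            "lipid metabolism", "glycolysis", "TCA cycle", "transport",
            "stress response", "development", "DNA synthesis",
            "amino acid metabolism", "major CHO metabolism",
            "secondary metabolism")
  if (nBins <= length(base)) base[seq_len(nBins)]
  else c(base, sprintf("category %02d", seq_len(nBins - length(base))))
}

#' Generate a seeded six-stage multi-omics dataset with known truth
#'
#' Produces an expression [StageExperiment-class] (6 stages x 3
#' replicates by default), a metabolite `StageExperiment` (6 x 6), the
#' annotation tables the downstream modules consume, and a ground-truth
#' record for parameter-recovery tests. Abundances follow a log2-normal
#' multiplicative noise model around planted stage-mean profiles, so all
#' values are strictly positive and the run is fully determined by the
#' seed.
#'
#' @param config a [simConfig()] object.
#' @return list with elements `expression`, `metabolites`
#'   (`StageExperiment`s), `annotation` (gene_id, bin_code, bin_name),
#'   `enzymeMap` (gene_id, metabolite_id, role), `pathwayEdges`
#'   (metabolite_a, metabolite_b), `truth` (list), and `config`.
#' @examples
#' d <- generateDataset(simConfig(nGenes = 300, nMetabolites = 6,
#'                                seed = 1))
#' d$expression
#' @export
generateDataset <- function(config) {
  if (!inherits(config, "SimConfig")) config <- do.call(simConfig, config)
  cfg <- config
  set.seed(cfg$seed)
  childSeeds <- sample.int(.Machine$integer.max - 1L, 6L)

  nStage <- 6L
  exprStage <- rep(seq_len(nStage), each = cfg$exprReplicates)
  metabStage <- rep(seq_len(nStage), each = cfg$metabReplicates)
  nExprSamp <- length(exprStage)

  geneIds <- sprintf("gene_%04d", seq_len(cfg$nGenes))
  nModGenes <- cfg$nModulesPlanted * cfg$moduleSize
  nEnzGenes <- cfg$nMetabolites * (1 + cfg$nDecoys)
  idxModule <- seq_len(nModGenes)
  idxEnzyme <- nModGenes + seq_len(nEnzGenes)
  idxTF <- nModGenes + nEnzGenes + seq_len(cfg$nSingleStageTF)
  idxCluster <- setdiff(seq_len(cfg$nGenes),
                        c(idxModule, idxEnzyme, idxTF))

  logExpr <- matrix(NA_real_, cfg$nGenes, nExprSamp,
                    dimnames = list(geneIds, NULL))

  ## --- child stream 1: stage-peaked cluster genes -------------------
  set.seed(childSeeds[1])
  clusterOf <- rep(seq_len(cfg$nClustersPlanted),
                   length.out = length(idxCluster))
  clusterPeak <- ((seq_len(cfg$nClustersPlanted) - 1L) %% nStage) + 1L
  ampC <- 3; widthC <- 0.75
  for (j in seq_along(idxCluster)) {
    cl <- clusterOf[j]
    prof <- ampC * exp(-((1:nStage) - clusterPeak[cl])^2 / (2 * widthC^2))
    base <- rnorm(1, 3, 1)
    logExpr[idxCluster[j], ] <- base + prof[exprStage] +
      rnorm(nExprSamp, 0, cfg$noiseSd)
  }

  ## --- child stream 2: coexpression-module genes --------------------
  set.seed(childSeeds[2])
  moduleStage <- ((seq_len(cfg$nModulesPlanted) - 1L) %% nStage) + 1L
  moduleOf <- rep(seq_len(cfg$nModulesPlanted), each = cfg$moduleSize)
  moduleLatent <- matrix(NA_real_, cfg$nModulesPlanted, nExprSamp)
  for (m in seq_len(cfg$nModulesPlanted)) {
    z <- as.numeric(scale(as.numeric(exprStage == moduleStage[m])))
    moduleLatent[m, ] <- blendLatent(z, cfg$moduleStageR)
  }
  ampM <- 2
  for (j in seq_along(idxModule)) {
    m <- moduleOf[j]
    base <- rnorm(1, 4, 1)
    logExpr[idxModule[j], ] <- base + ampM * moduleLatent[m, ] +
      rnorm(nExprSamp, 0, cfg$noiseSd)
  }

  ## --- child stream 3: single-stage transcription factors -----------
  set.seed(childSeeds[3])
  tfStage <- rep(seq_len(nStage), length.out = cfg$nSingleStageTF)
  for (j in seq_along(idxTF)) {
    prof <- ifelse(1:nStage == tfStage[j], log2(30), log2(0.02))
    logExpr[idxTF[j], ] <- prof[exprStage] +
      rnorm(nExprSamp, 0, cfg$noiseSd)
  }

  ## --- child stream 4: metabolites + enzyme families ----------------
  set.seed(childSeeds[4])
  metabIds <- sprintf("met_%03d", seq_len(cfg$nMetabolites))
  chainLen <- 3L
  chainOf <- (seq_len(cfg$nMetabolites) - 1L) %/% chainLen
  traj <- matrix(NA_real_, cfg$nMetabolites, nStage,
                 dimnames = list(metabIds, NULL))
  wAdj <- 0.95  # latent sharing along pathway chains
  for (i in seq_len(cfg$nMetabolites)) {
    traj[i, ] <- if (i > 1 && chainOf[i] == chainOf[i - 1])
      blendLatent(traj[i - 1, ], wAdj) else smoothTrajectory()
  }
  ampT <- 1.5
  logMetab <- matrix(NA_real_, cfg$nMetabolites, length(metabStage),
                     dimnames = list(metabIds, NULL))
  for (i in seq_len(cfg$nMetabolites)) {
    base <- rnorm(1, 10, 1)
    logMetab[i, ] <- base + ampT * traj[i, metabStage] +
      rnorm(length(metabStage), 0, cfg$noiseSd)
  }
  pathwayEdges <- data.frame(
    metabolite_a = metabIds[which(diff(chainOf) == 0)],
    metabolite_b = metabIds[which(diff(chainOf) == 0) + 1L],
    stringsAsFactors = FALSE)

  famSize <- 1 + cfg$nDecoys
  wCausal <- rhoSpearmanToPearson(cfg$causalGeneRho, nStage)
  ampG <- 3
  causalGene <- character(cfg$nMetabolites)
  enzymeMap <- vector("list", cfg$nMetabolites)
  for (i in seq_len(cfg$nMetabolites)) {
    fam <- geneIds[idxEnzyme[(i - 1L) * famSize + seq_len(famSize)]]
    causal <- fam[sample.int(famSize, 1)]
    causalGene[i] <- causal
    for (g in fam) {
      gTraj <- if (g == causal) blendLatent(traj[i, ], wCausal)
               else as.numeric(scale(rnorm(nStage)))
      base <- rnorm(1, 4, 1)
      logExpr[g, ] <- base + ampG * gTraj[exprStage] +
        rnorm(nExprSamp, 0, cfg$noiseSd)
    }
    enzymeMap[[i]] <- data.frame(
      gene_id = fam, metabolite_id = metabIds[i],
      role = sample(c("synthesis", "decomposition"), famSize,
                    replace = TRUE),
      stringsAsFactors = FALSE)
  }
  enzymeMap <- do.call(rbind, enzymeMap)

  ## --- child stream 5: annotation bins ------------------------------
  set.seed(childSeeds[5])
  binCodes <- sprintf("bin%02d", seq_len(cfg$nBins))
  bnames <- binNames(cfg$nBins)
  pEnr <- min(0.9, cfg$enrichmentFold / cfg$nBins)
  binOf <- character(cfg$nGenes)
  inCluster1 <- logical(cfg$nGenes)
  inCluster1[idxCluster[clusterOf == 1L]] <- TRUE
  for (g in seq_len(cfg$nGenes)) {
    binOf[g] <- if (inCluster1[g]) {
      if (runif(1) < pEnr) binCodes[1]
      else sample(binCodes[-1], 1)
    } else sample(binCodes, 1)
  }
  annotation <- data.frame(gene_id = geneIds, bin_code = binOf,
                           bin_name = bnames[match(binOf, binCodes)],
                           stringsAsFactors = FALSE)

  expression <- StageExperiment(2^logExpr, exprStage, assayName = "fpkm")
  metabolites <- StageExperiment(2^logMetab, metabStage)

  dirs <- apply(traj, 1, function(tr) {
    d <- ampT * (tr - tr[1])
    ifelse(abs(d) < 0.5, "flat", ifelse(d > 0, "up", "down"))
  })
  truth <- list(
    clusterOf = as.list(setNames(clusterOf, geneIds[idxCluster])),
    clusterPeakStage = as.list(setNames(clusterPeak,
                                        seq_len(cfg$nClustersPlanted))),
    moduleOf = as.list(setNames(moduleOf, geneIds[idxModule])),
    moduleStage = as.list(setNames(moduleStage,
                                   seq_len(cfg$nModulesPlanted))),
    binOf = as.list(setNames(binOf, geneIds)),
    causalGene = as.list(setNames(causalGene, metabIds)),
    metaboliteDirection = as.list(as.data.frame(dirs,
                                                stringsAsFactors = FALSE)),
    singleStageTF = as.list(setNames(tfStage, geneIds[idxTF])),
    enrichedBin = list(cluster = 1, bin = binCodes[1],
                       fold = cfg$enrichmentFold))
  list(expression = expression, metabolites = metabolites,
       annotation = annotation, enzymeMap = enzymeMap,
       pathwayEdges = pathwayEdges, truth = truth, config = cfg)
}

#' Generate a synthetic triphasic imbibition (fresh-weight) series
#'
#' Piecewise-linear mean, continuous at the breakpoints, plus additive
#' Gaussian noise: the classical rapid-uptake / plateau / renewed-uptake
#' shape of a germinating seed's fresh-weight curve.
#'
#' @param breakpoints two strictly increasing times (minutes) inside the
#'   observed range.
#' @param slopes three segment slopes (g/min); the first must exceed the
#'   second (rapid then slow water uptake).
#' @param noiseSd additive noise s.d. (grams).
#' @param nPoints number of equally spaced time points.
#' @param tMax last time point (minutes).
#' @param w0 starting weight (grams).
#' @param seed integer seed.
#' @return data.frame with columns `time_min`, `weight_g`.
#' @export
generateImbibitionSeries <- function(breakpoints = c(120, 600),
                                     slopes = c(0.004, 0.001, 0.003),
                                     noiseSd = 0.001, nPoints = 109,
                                     tMax = 1080, w0 = 1, seed = 1) {
  if (length(breakpoints) != 2 || any(diff(breakpoints) <= 0) ||
      breakpoints[1] <= 0 || breakpoints[2] >= tMax)
    stop(germError("breakpoints must be strictly increasing inside the time range",
                   "germConfigError"))
  if (length(slopes) != 3 || slopes[1] <= slopes[2])
    stop(germError("need slope1 > slope2 (rapid then slow uptake)",
                   "germConfigError"))
  set.seed(seed)
  tm <- seq(0, tMax, length.out = nPoints)
  mu <- w0 + slopes[1] * pmin(tm, breakpoints[1]) +
    slopes[2] * pmax(0, pmin(tm, breakpoints[2]) - breakpoints[1]) +
    slopes[3] * pmax(0, tm - breakpoints[2])
  data.frame(time_min = tm,
             weight_g = mu + rnorm(nPoints, 0, noiseSd))
}
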