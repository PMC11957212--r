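#' Configuration for the two-population synthetic generator
#'
#' Defines the study conditions every synthetic experiment runs under: a
#' Balding-Nichols two-population differentiation model with autoregressive
#' within-gene LD, sparse cis-eQTL architecture shared between populations,
#' population-specific sparse weight training, and a GReX-mediated trait.
#'
#' @param n_genes number of gene blocks.
#' @param snps_per_gene SNPs per gene block (cis-window SNP count).
#' @param ld_rho length-2 vector in [0, 1): AR(1) latent correlation of the
#'   haplotype model per population; population A defaults to high LD (0.8),
#'   population B to moderate LD (0.3).
#' @param fst Balding-Nichols differentiation parameter in (0, 1).
#' @param maf_range ancestral allele-frequency bounds.
#' @param n_causal_eqtl_per_gene causal cis-eQTLs per gene (effects shared
#'   across populations).
#' @param h2_expr proportion of expression variance explained by the causal
#'   cis SNPs, in [0, 1).
#' @param prop_causal_genes proportion of genes with a nonzero gene-trait
#'   effect.
#' @param h2_trait proportion of trait variance explained by the causal
#'   GReX, in [0, 1). Must be 0 when \code{prop_causal_genes} is 0 is not
#'   required; with zero causal genes the trait is pure noise.
#' @param n_train training cohort size per population.
#' @param n_gwas GWAS cohort size (a 50/50 mixture of the two populations,
#'   emulating a multi-ancestry meta-analysis).
#' @param weight_method \code{"topk_marginal"} (select k SNPs by marginal
#'   training-cohort correlation with expression, then joint least squares)
#'   or \code{"coordinate_lasso"} (glmnet lasso path, sparsest fit within 1
#'   SE of the CV optimum).
#' @param k_snps length-2 vector: SNPs selected per gene in each population's
#'   model under \code{topk_marginal}; defaults 28 and 8, the per-model
#'   median feature counts the admixed and European whole-blood models
#'   realize in practice.
#' @param model_ids labels for the two population models.
#' @param seed integer; fixes every downstream draw.
#' @return validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(n_genes = 100, snps_per_gene = 30,
                      ld_rho = c(0.8, 0.3), fst = 0.15,
                      maf_range = c(0.05, 0.5),
                      n_causal_eqtl_per_gene = 3, h2_expr = 0.25,
                      prop_causal_genes = 0.2, h2_trait = 0.3,
                      n_train = 400, n_gwas = 2000,
                      weight_method = c("topk_marginal", "coordinate_lasso"),
                      k_snps = c(28, 8), model_ids = c("popA", "popB"),
                      seed = 42) {
  weight_method <- match.arg(weight_method)
  cfg <- list(n_genes = as.integer(n_genes),
              snps_per_gene = as.integer(snps_per_gene),
              ld_rho = as.numeric(ld_rho), fst = as.numeric(fst),
              maf_range = as.numeric(maf_range),
              n_causal_eqtl_per_gene = as.integer(n_causal_eqtl_per_gene),
              h2_expr = as.numeric(h2_expr),
              prop_causal_genes = as.numeric(prop_causal_genes),
              h2_trait = as.numeric(h2_trait),
              n_train = as.integer(n_train), n_gwas = as.integer(n_gwas),
              weight_method = weight_method,
              k_snps = pmin(as.integer(k_snps), as.integer(snps_per_gene)),
              model_ids = as.character(model_ids),
              seed = as.integer(seed))
  ok <- function(x, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    all(x > lo | (!lo_open & x == lo)) && all(x < hi | (!hi_open & x == hi))
  }
  if (cfg$n_genes < 1 || cfg$snps_per_gene < 1 || cfg$n_train < 2 ||
      cfg$n_gwas < 4) {
    stop_admixtwas("cohort and panel sizes too small", "config_error")
  }
  if (length(cfg$ld_rho) != 2 || !ok(cfg$ld_rho, 0, 1, hi_open = TRUE)) {
    stop_admixtwas("ld_rho must be two values in [0, 1)", "config_error")
  }
  if (!ok(cfg$fst, 0, 1, lo_open = TRUE, hi_open = TRUE)) {
    stop_admixtwas("fst must lie in (0, 1)", "config_error")
  }
  if (!ok(cfg$h2_expr, 0, 1, hi_open = TRUE) ||
      !ok(cfg$h2_trait, 0, 1, hi_open = TRUE) ||
      !ok(cfg$prop_causal_genes, 0, 1)) {
    stop_admixtwas("variance proportions out of range", "config_error")
  }
  if (cfg$h2_trait == 0 && cfg$prop_causal_genes > 0) {
    stop_admixtwas(
      "h2_trait = 0 with causal genes present is contradictory",
      "config_error")
  }
  if (cfg$n_causal_eqtl_per_gene < 1 ||
      cfg$n_causal_eqtl_per_gene > cfg$snps_per_gene) {
    stop_admixtwas("n_causal_eqtl_per_gene out of range", "config_error")
  }
  class(cfg) <- "SimConfig"
  cfg
}

# AR(1) latent-Gaussian haplotypes thresholded at qnorm(freq): allele j has
# frequency freq[j], neighbouring alleles correlate through rho.
.sim_dosage <- function(n, freqs, rho) {
  m <- length(freqs)
  hap <- function() {
    z <- matrix(stats::rnorm(n * m), n, m)
    if (rho > 0 && m > 1) {
      for (j in 2:m) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
    }
    sweep(z, 2, stats::qnorm(freqs), "<") + 0L
  }
  x <- hap() + hap()
  storage.mode(x) <- "integer"
  x
}

#' Simulate the two-population genotype panel
#'
#' Ancestral allele frequencies are uniform on \code{maf_range}; each
#' population's frequency is Balding-Nichols,
#' \eqn{p_k \sim \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)}, redrawn (up to 20
#' times, then an error) if it leaves [0.01, 0.99]. Haplotypes are
#' thresholded AR(1)-correlated latent Gaussians per gene block, giving
#' dosages in \{0, 1, 2\} with tractable block LD; dosage counts the effect
#' allele. Three cohorts are drawn: one training cohort per population and a
#' GWAS cohort mixing the two populations 50/50.
#'
#' @param cfg a [simConfig()].
#' @return list of class \code{"SimPanel"}: \code{snps} (per-SNP table with
#'   gene, alleles, population frequencies), \code{gene_positions}, and
#'   per-gene dosage matrices \code{X_trainA}, \code{X_trainB},
#'   \code{X_gwas} (named lists of integer matrices, SNP ids as colnames).
#' @export
simulatePanel <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  ng <- cfg$n_genes; m <- cfg$snps_per_gene
  bases <- c("A", "C", "G", "T")
  draw_freq <- function(p, fst) {
    a <- p * (1 - fst) / fst
    b <- (1 - p) * (1 - fst) / fst
    for (try in 1:20) {
      f <- stats::rbeta(1, a, b)
      if (f >= 0.01 && f <= 0.99) return(f)
    }
    stop_admixtwas("could not draw a polymorphic population frequency",
                   "config_error")
  }
  genes <- sprintf("ENSG%08d", seq_len(ng))
  snp_rows <- vector("list", ng)
  X_trainA <- X_trainB <- X_gwas <- stats::setNames(vector("list", ng), genes)
  n_gwas_a <- cfg$n_gwas %/% 2
  for (g in seq_len(ng)) {
    ids <- sprintf("rs%07d", (g - 1L) * m + seq_len(m))
    ref <- sample(bases, m, replace = TRUE)
    eff <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    p_anc <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    fA <- vapply(p_anc, draw_freq, numeric(1), fst = cfg$fst)
    fB <- vapply(p_anc, draw_freq, numeric(1), fst = cfg$fst)
    snp_rows[[g]] <- data.frame(
      gene = genes[g], snp_id = ids, chrom = "1",
      pos = 2e6 * g + 100 * seq_len(m), ref_allele = ref, eff_allele = eff,
      freq_anc = p_anc, freq_a = fA, freq_b = fB, stringsAsFactors = FALSE)
    mk <- function(x, ids) { colnames(x) <- ids; x }
    X_trainA[[g]] <- mk(.sim_dosage(cfg$n_train, fA, cfg$ld_rho[1]), ids)
    X_trainB[[g]] <- mk(.sim_dosage(cfg$n_train, fB, cfg$ld_rho[2]), ids)
    X_gwas[[g]] <- mk(rbind(
      .sim_dosage(n_gwas_a, fA, cfg$ld_rho[1]),
      .sim_dosage(cfg$n_gwas - n_gwas_a, fB, cfg$ld_rho[2])), ids)
    if (g == 1L) {
      gwas_pop <- rep(c("A", "B"), c(n_gwas_a, cfg$n_gwas - n_gwas_a))
    }
  }
  snps <- do.call(rbind, snp_rows)
  gene_positions <- data.frame(
    gene = genes, chrom = "1", start = 2e6 * seq_len(ng) + 100,
    end = 2e6 * seq_len(ng) + 100 * m, stringsAsFactors = FALSE)
  structure(list(cfg = cfg, genes = genes, snps = snps,
                 gene_positions = gene_positions,
                 X_trainA = X_trainA, X_trainB = X_trainB, X_gwas = X_gwas,
                 gwas_pop = gwas_pop),
            class = "SimPanel")
}

# top-k marginal selection + joint OLS; returns named weight vector
.fit_topk <- function(X, e, k) {
  sds <- apply(X, 2, stats::sd)
  usable <- sds > 0
  if (!any(usable)) return(numeric())
  cors <- rep(0, ncol(X))
  cors[usable] <- abs(stats::cor(X[, usable, drop = FALSE], e))
  sel <- order(cors, decreasing = TRUE)[seq_len(min(k, sum(usable)))]
  sel <- sel[cors[sel] > 0]
  if (!length(sel)) return(numeric())
  cf <- qr.coef(qr(cbind(1, X[, sel, drop = FALSE])), e)[-1]
  names(cf) <- colnames(X)[sel]
  cf <- cf[is.finite(cf) & cf != 0]
  cf
}

.fit_lasso <- function(X, e, ...) {
  if (!requireNamespace("glmnet", quietly = TRUE)) {
    stop_admixtwas("weight_method 'coordinate_lasso' requires glmnet",
                   "config_error")
  }
  fit <- glmnet::cv.glmnet(X, e, alpha = 1, nfolds = 5)
  cf <- as.matrix(stats::coef(fit, s = "lambda.1se"))[-1, 1]
  names(cf) <- colnames(X)
  cf[cf != 0]
}

#' Simulate expression and train population-specific weight models
#'
#' Each gene receives \code{n_causal_eqtl_per_gene} causal cis-eQTLs with
#' normal effects shared between populations. Expression in a cohort is
#' \eqn{e = \sqrt{h^2}\, \tilde g + \sqrt{1-h^2}\,\varepsilon} with
#' \eqn{\tilde g} the standardized causal dosage score. Per population a
#' sparse weight model is trained on that population's cohort; under
#' \code{topk_marginal} the selected set is the k SNPs with the largest
#' absolute marginal correlation, refit jointly by least squares.
#' Cross-validated r-squared is computed by 5-fold CV with selection redone
#' inside each training fold (no selection leakage). A gene for which
#' training selects no SNP is omitted from that model, which is how
#' single-model ("A only"/"B only") genes arise.
#'
#' @param panel a [simulatePanel()] result.
#' @param cfg the same [simConfig()].
#' @return list: \code{models} (two \linkS4class{PredictionModel}s named by
#'   \code{cfg$model_ids}), \code{truth} (per-gene causal SNP ids/effects,
#'   gene-trait effects \code{alpha}), and \code{overlap} (per-gene shared
#'   SNP counts and Jaccard between the two trained models).
#' @export
simulateExpressionAndWeights <- function(panel, cfg) {
  stopifnot(inherits(panel, "SimPanel"))
  set.seed(cfg$seed + 1L)
  ng <- cfg$n_genes
  n_causal_genes <- round(cfg$prop_causal_genes * ng)
  causal_genes <- if (n_causal_genes) sort(sample(ng, n_causal_genes))
                  else integer()
  alpha <- numeric(ng)
  if (length(causal_genes)) alpha[causal_genes] <- stats::rnorm(n_causal_genes)
  fitter <- if (cfg$weight_method == "topk_marginal") .fit_topk else .fit_lasso
  wrows <- list(); grows <- list()
  truth_genes <- vector("list", ng)
  for (g in seq_len(ng)) {
    m <- cfg$snps_per_gene
    causal <- sort(sample(m, cfg$n_causal_eqtl_per_gene))
    beta <- stats::rnorm(cfg$n_causal_eqtl_per_gene)
    snps_g <- panel$snps[panel$snps$gene == panel$genes[g], , drop = FALSE]
    truth_genes[[g]] <- list(gene = panel$genes[g],
                             causal_snps = snps_g$snp_id[causal],
                             beta = beta, alpha = alpha[g])
    for (pop in 1:2) {
      X <- if (pop == 1) panel$X_trainA[[g]] else panel$X_trainB[[g]]
      gs <- drop(X[, causal, drop = FALSE] %*% beta)
      gsd <- stats::sd(gs)
      gstd <- if (gsd > 0) (gs - mean(gs)) / gsd else gs * 0
      e <- sqrt(cfg$h2_expr) * gstd +
        sqrt(1 - cfg$h2_expr) * stats::rnorm(cfg$n_train)
      w <- fitter(X, e, cfg$k_snps[pop])
      if (!length(w)) next
      # 5-fold CV with per-fold reselection
      fold <- sample(rep(1:5, length.out = cfg$n_train))
      pred <- rep(NA_real_, cfg$n_train)
      for (f in 1:5) {
        tr <- fold != f
        wf <- fitter(X[tr, , drop = FALSE], e[tr], cfg$k_snps[pop])
        if (!length(wf)) { pred[!tr] <- mean(e[tr]); next }
        pred[!tr] <- drop(X[!tr, names(wf), drop = FALSE] %*% wf)
      }
      cv_r2 <- if (stats::sd(pred) > 0) stats::cor(pred, e)^2 else 0
      sel <- match(names(w), snps_g$snp_id)
      wrows[[length(wrows) + 1L]] <- data.frame(
        pop = pop, gene = panel$genes[g], snp_id = names(w),
        chrom = snps_g$chrom[sel], pos = snps_g$pos[sel],
        ref_allele = snps_g$ref_allele[sel],
        eff_allele = snps_g$eff_allele[sel],
        weight = unname(w), stringsAsFactors = FALSE)
      grows[[length(grows) + 1L]] <- data.frame(
        pop = pop, gene = panel$genes[g],
        gene_name = sprintf("GENE%d", g), cv_r2 = min(max(cv_r2, 0), 1),
        stringsAsFactors = FALSE)
    }
  }
  wall <- do.call(rbind, wrows)
  gall <- do.call(rbind, grows)
  models <- lapply(1:2, function(pop) {
    PredictionModel(cfg$model_ids[pop],
                    paste0("synthetic population ", c("A", "B")[pop]),
                    weights = wall[wall$pop == pop,
                                   setdiff(names(wall), "pop")],
                    genes = gall[gall$pop == pop,
                                 setdiff(names(gall), "pop")])
  })
  names(models) <- cfg$model_ids
  overlap <- snpSetOverlap(models[[1]], models[[2]])
  list(models = models,
       truth = list(genes = truth_genes, alpha = alpha,
                    causal_genes = panel$genes[causal_genes]),
       overlap = overlap)
}

#' Per-gene SNP-set overlap between two models
#'
#' @param modelA,modelB \linkS4class{PredictionModel}s.
#' @return data.frame \code{gene, n_a, n_b, n_shared, jaccard} over genes
#'   present in both models.
#' @export
snpSetOverlap <- function(modelA, modelB) {
  co <- intersect(geneIds(modelA), geneIds(modelB))
  wa <- split(snpWeights(modelA)$snp_id, snpWeights(modelA)$gene)
  wb <- split(snpWeights(modelB)$snp_id, snpWeights(modelB)$gene)
  out <- lapply(co, function(g) {
    a <- wa[[g]]; b <- wb[[g]]
    sh <- length(intersect(a, b))
    data.frame(gene = g, n_a = length(a), n_b = length(b), n_shared = sh,
               jaccard = sh / length(union(a, b)), stringsAsFactors = FALSE)
  })
  if (!length(out)) {
    return(data.frame(gene = character(), n_a = integer(), n_b = integer(),
                      n_shared = integer(), jaccard = numeric()))
  }
  do.call(rbind, out)
}

#' Simulate a GReX-mediated trait and its GWAS summary statistics
#'
#' The phenotype is \eqn{y = \sqrt{h^2_t}\,\tilde G + \sqrt{1-h^2_t}\,
#' \varepsilon} in the GWAS cohort, where \eqn{\tilde G} is the standardized
#' sum over causal genes of \eqn{\alpha_g} times that gene's standardized
#' true GReX (causal dosages times causal effects). With zero causal genes
#' the trait is pure noise. Per-SNP summary statistics come from linear
#' regression of \eqn{y} on dosage adjusted for the population indicator
#' (dosage and phenotype are residualized within population before the
#' regression), the standard guard against stratification confounding in a
#' mixed-ancestry cohort; each record's allele encoding is randomly swapped
#' (z and beta negated) with probability 1/2 so that harmonization is
#' exercised. SNPs with no within-population dosage variance are absent
#' from the output, as in a real association scan.
#'
#' @param panel a [simulatePanel()] result.
#' @param truth the \code{truth} component of
#'   [simulateExpressionAndWeights()].
#' @param cfg the same [simConfig()].
#' @param traitId trait label (default \code{"SIM"}).
#' @param seed RNG seed for the trait draw; defaults to \code{cfg$seed + 2}.
#'   Passing distinct seeds (and, if desired, modified \code{truth$genes}
#'   alpha values) simulates several traits over the same panel and models.
#' @return list: \code{gwas} (a \linkS4class{GwasSumStats}),
#'   \code{phenotypes} (the individual-level y, for the oracle).
#' @export
simulateTraitGwas <- function(panel, truth, cfg, traitId = "SIM",
                              seed = cfg$seed + 2L) {
  stopifnot(inherits(panel, "SimPanel"))
  set.seed(seed)
  n <- cfg$n_gwas
  G <- numeric(n)
  any_causal <- FALSE
  for (tg in truth$genes) {
    if (tg$alpha == 0) next
    X <- panel$X_gwas[[tg$gene]]
    gs <- drop(X[, tg$causal_snps, drop = FALSE] %*% tg$beta)
    gsd <- stats::sd(gs)
    if (gsd > 0) { G <- G + tg$alpha * (gs - mean(gs)) / gsd
                   any_causal <- TRUE }
  }
  y <- if (any_causal && cfg$h2_trait > 0) {
    sqrt(cfg$h2_trait) * (G - mean(G)) / stats::sd(G) +
      sqrt(1 - cfg$h2_trait) * stats::rnorm(n)
  } else stats::rnorm(n)
  pop <- panel$gwas_pop
  yc <- y - stats::ave(y, pop)
  sy <- stats::sd(yc)
  recs <- vector("list", length(panel$genes))
  for (g in seq_along(panel$genes)) {
    X <- panel$X_gwas[[g]]
    Xc <- apply(X, 2, function(col) col - stats::ave(col, pop))
    sx <- apply(Xc, 2, stats::sd)
    poly <- sx > 0
    if (!any(poly)) next
    r <- drop(stats::cor(Xc[, poly, drop = FALSE], yc))
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    beta <- r * sy / sx[poly]
    se <- sy / sx[poly] * sqrt((1 - r^2) / (n - 3))
    sg <- panel$snps[panel$snps$gene == panel$genes[g], ][poly, ]
    recs[[g]] <- data.frame(
      snp_id = sg$snp_id, chrom = sg$chrom, pos = sg$pos,
      a1 = sg$eff_allele, a2 = sg$ref_allele, beta = beta, se = se,
      stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, recs)
  swap <- stats::runif(nrow(rec)) < 0.5
  tmp <- rec$a1[swap]; rec$a1[swap] <- rec$a2[swap]; rec$a2[swap] <- tmp
  rec$beta[swap] <- -rec$beta[swap]
  rec$zscore <- rec$beta / rec$se
  rec$n <- n
  rownames(rec) <- NULL
  list(gwas = GwasSumStats(traitId, rec), phenotypes = y)
}

#' Empirical LD reference covariance for a model
#'
#' Per model gene, the empirical dosage covariance of the model's SNPs in a
#' designated reference cohort (conventionally the model's own training
#' population).
#'
#' @param panel a [simulatePanel()] result.
#' @param model a \linkS4class{PredictionModel} whose SNPs are in the panel.
#' @param cohort \code{"trainA"}, \code{"trainB"} or \code{"gwas"}.
#' @return a \linkS4class{CovarianceTable}.
#' @export
computeReferenceCovariance <- function(panel, model,
                                       cohort = c("trainA", "trainB",
                                                  "gwas")) {
  cohort <- match.arg(cohort)
  Xs <- panel[[paste0("X_", cohort)]]
  entries <- list()
  for (g in geneIds(model)) {
    feats <- snpWeights(model, g)
    X <- Xs[[g]]
    if (is.null(X)) {
      stop_admixtwas(paste0("gene ", g, " absent from panel"),
                     "validity_error")
    }
    missing_snps <- setdiff(feats$snp_id, colnames(X))
    if (length(missing_snps)) {
      stop_admixtwas(paste0("SNP(s) missing from panel for gene ", g, ": ",
                            paste(missing_snps, collapse = ", ")),
                     "validity_error", snps = missing_snps)
    }
    if (nrow(X) < 2) {
      stop_admixtwas("covariance undefined for a single-individual cohort",
                     "validity_error")
    }
    entries[[g]] <- stats::cov(X[, feats$snp_id, drop = FALSE])
  }
  CovarianceTable(entries)
}

#' Individual-level TWAS oracle
#'
#' The statistic the summary-level engine approximates: per gene, predicted
#' expression is the dosage-weight product per individual, and the oracle z
#' is the t-statistic of the regression of the phenotype on predicted
#' expression, with the same population-indicator adjustment the simulated
#' GWAS applies (both sides residualized within population). Genes with
#' zero-variance prediction are skipped.
#'
#' @param panel a [simulatePanel()] result.
#' @param model a \linkS4class{PredictionModel}.
#' @param phenotypes numeric vector, GWAS-cohort phenotype.
#' @return data.frame \code{gene, oracle_z, n_snps}; skipped genes carry
#'   \code{NA} oracle_z.
#' @export
individualOracleTwas <- function(panel, model, phenotypes) {
  n <- length(phenotypes)
  pop <- panel$gwas_pop
  yc <- phenotypes - stats::ave(phenotypes, pop)
  out <- lapply(geneIds(model), function(g) {
    feats <- snpWeights(model, g)
    X <- panel$X_gwas[[g]]
    pred <- drop(X[, feats$snp_id, drop = FALSE] %*% feats$weight)
    predc <- pred - stats::ave(pred, pop)
    if (stats::sd(predc) == 0) {
      return(data.frame(gene = g, oracle_z = NA_real_,
                        n_snps = nrow(feats)))
    }
    r <- stats::cor(predc, yc)
    data.frame(gene = g, oracle_z = r * sqrt(n - 3) / sqrt(1 - r^2),
               n_snps = nrow(feats), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
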