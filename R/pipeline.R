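#' @include io.R
NULL

md5OfObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes, in order: synthetic-data generation, inverse-normal transform,
#' per-condition cis-eQTL mapping, conditional signal dissection for
#' multi-signal eGenes, response-eQTL testing per cell type, trans scans,
#' mediation of trans hits through cis genes, colocalisation against the
#' simulated GWAS, Mendelian randomisation for eGenes with enough
#' instruments, and pi1 replication between the paired conditions.  Any
#' stage may be skipped; stages needing a skipped stage's output refuse to
#' run.
#'
#' @param cfg a [SimConfig-class] (its seed drives every stage).
#' @param stages character vector of stages to run (default all):
#'   `simulate`, `preprocess`, `cis`, `signals`, `reqtl`, `trans`,
#'   `mediate`, `coloc`, `mr`, `pi1`.
#' @param fdr FDR level used throughout (default 0.05).
#' @param nPerm response-eQTL permutations (default 1000).
#' @param nBoot mediation bootstrap replicates (default 10000).
#' @param nGwas simulated GWAS cohort size (default 20000).
#' @param outDir optional directory; when given, stage outputs are written
#'   as TSV/JSON.
#' @return list with per-stage `results` and a `manifest` (config snapshot,
#'   stage seeds, row counts, output hashes); re-running with the same
#'   configuration reproduces identical manifest hashes.
#' @export
runPipeline <- function(cfg, stages = c("simulate", "preprocess", "cis",
                                        "signals", "reqtl", "trans",
                                        "mediate", "coloc", "mr", "pi1"),
                        fdr = 0.05, nPerm = 1000L, nBoot = 10000L,
                        nGwas = 20000L, outDir = NULL) {
  res <- list()
  counts <- list()
  needs <- function(stage, what) {
    if (is.null(res[[what]]))
      stop("stage '", stage, "' needs output of skipped stage '", what, "'")
  }
  ct <- cfg@conditionTable
  if ("simulate" %in% stages) {
    sim <- simulateStudy(cfg)
    sim$gwas <- simulateGwas(sim$panel, sim$truth, nGwas = nGwas,
                             seed = stageSeed(cfg@seed, "gwas"))
    res$simulate <- sim
    counts$simulate <- c(snps = ncol(dosages(sim$panel)),
                         genes = nrow(sim$genes),
                         samples = nrow(sampleSheet(sim$study)))
  }
  if ("preprocess" %in% stages) {
    needs("preprocess", "simulate")
    res$preprocess <- intTransformStudy(res$simulate$study)
    counts$preprocess <- c(samples = nrow(sampleSheet(res$preprocess)))
  }
  if ("cis" %in% stages) {
    needs("cis", "preprocess")
    study <- res$preprocess; panel <- res$simulate$panel
    res$cis <- lapply(setNames(ct$condition, ct$condition), function(cond)
      mapCisEqtls(study, panel, cond, fdr = fdr))
    counts$cis <- vapply(res$cis, function(x) sum(x$egenes$is_egene),
                         numeric(1))
  }
  if ("signals" %in% stages) {
    needs("signals", "cis")
    study <- res$preprocess; panel <- res$simulate$panel
    res$signals <- list()
    for (cond in ct$condition) {
      eg <- res$cis[[cond]]$egenes
      sig <- eg[eg$is_egene, , drop = FALSE]
      out <- lapply(seq_len(nrow(sig)), function(i)
        independentSignals(study, panel, cond, sig$gene_id[i],
                           sig$top_snp[i], sig$nominal_threshold[i]))
      res$signals[[cond]] <- if (length(out)) do.call(rbind, out) else NULL
    }
    counts$signals <- vapply(res$signals, function(x)
      if (is.null(x)) 0 else nrow(x), numeric(1))
  }
  if ("reqtl" %in% stages) {
    needs("reqtl", "cis")
    study <- res$preprocess; panel <- res$simulate$panel
    res$reqtl <- list()
    for (cell in unique(ct$cell_type)) {
      conds <- ct$condition[ct$cell_type == cell]
      rest <- conds[ct$treatment[ct$cell_type == cell] == "resting"]
      stim <- conds[ct$treatment[ct$cell_type == cell] == "stimulated"]
      tests <- selectReqtlTests(res$cis[[rest]]$egenes,
                                res$cis[[stim]]$egenes, panel)
      if (nrow(tests) == 0L) next
      sc <- reqtlScan(study, panel, cell, tests, nPerm = nPerm,
                      seed = stageSeed(cfg@seed, paste0("reqtl_", cell)))
      res$reqtl[[cell]] <- reqtlFdr(sc, alpha = fdr)
    }
    counts$reqtl <- vapply(res$reqtl, nrow, numeric(1))
  }
  if ("trans" %in% stages) {
    needs("trans", "preprocess")
    study <- res$preprocess; panel <- res$simulate$panel
    res$trans <- lapply(setNames(ct$condition, ct$condition), function(cond) {
      sc <- transScan(study, panel, cond)
      transMultipleTesting(sc, nGenes = nrow(geneInfo(study)), fdr = fdr)
    })
    counts$trans <- vapply(res$trans, function(x)
      sum(x$genomewide_fdr_sig), numeric(1))
  }
  if ("mediate" %in% stages) {
    needs("mediate", "trans"); needs("mediate", "cis")
    study <- res$preprocess; panel <- res$simulate$panel
    res$mediate <- list()
    for (cond in ct$condition) {
      hits <- res$trans[[cond]]
      hits <- hits[hits$genomewide_fdr_sig, , drop = FALSE]
      trios <- linkTransToCis(hits, res$cis[[cond]]$esnps)
      if (nrow(trios) == 0L) next
      trios$condition <- cond
      res$mediate[[cond]] <- mediationFdr(
        study, panel, trios, nBoot = nBoot,
        seed = stageSeed(cfg@seed, paste0("mediate_", cond)))
    }
    counts$mediate <- vapply(res$mediate, nrow, numeric(1))
  }
  if ("coloc" %in% stages) {
    needs("coloc", "cis")
    panel <- res$simulate$panel
    snps <- snpInfo(panel)
    res$coloc <- list()
    for (cond in ct$condition) {
      for (dis in names(res$simulate$gwas)) {
        gwas <- harmoniseGwasToPanel(res$simulate$gwas[[dis]], snps)
        loci <- selectColocLoci(res$cis[[cond]]$egenes,
                                res$cis[[cond]]$esnps, gwas, snps)
        loci <- loci[loci$status == "selected", , drop = FALSE]
        for (i in seq_len(nrow(loci))) {
          g <- loci$gene_id[i]
          assoc <- res$cis[[cond]]$assoc
          eq <- assoc[assoc$gene_id == g &
                      assoc$snp_id %in% loci$snp_ids[[i]], ]
          cp <- colocPosteriors(eq, gwas[gwas$snp_id %in% loci$snp_ids[[i]], ])
          res$coloc[[paste(cond, dis, g, sep = ".")]] <-
            c(list(gene = g, condition = cond, disease = dis), cp)
        }
      }
    }
    counts$coloc <- length(res$coloc)
  }
  if ("mr" %in% stages) {
    needs("mr", "cis")
    panel <- res$simulate$panel
    snps <- snpInfo(panel)
    res$mr <- list()
    for (cond in ct$condition) {
      esnps <- res$cis[[cond]]$esnps
      assoc <- res$cis[[cond]]$assoc
      for (dis in names(res$simulate$gwas)) {
        gwas <- res$simulate$gwas[[dis]]
        for (g in names(esnps)) {
          rows <- assoc[assoc$gene_id == g & assoc$snp_id %in% esnps[[g]], ]
          m <- match(rows$snp_id, snps$snp_id)
          expo <- data.frame(snp_id = rows$snp_id,
                             effect_allele = snps$alt[m],
                             other_allele = snps$ref[m], beta = rows$beta,
                             se = rows$se, p = rows$p,
                             stringsAsFactors = FALSE)
          cand <- tryCatch(harmoniseInstruments(expo, gwas),
                           error = function(e) NULL)
          if (is.null(cand)) next
          ivs <- suppressMessages(ldPruneInstruments(cand, panel))
          if (nrow(ivs) < 3L) next
          est <- mrEstimates(ivs, seed = stageSeed(cfg@seed, paste0("mr", g)))
          res$mr[[paste(cond, dis, g, sep = ".")]] <-
            list(gene = g, condition = cond, disease = dis,
                 estimates = est, verdict = mrVerdict(est))
        }
      }
    }
    counts$mr <- length(res$mr)
  }
  if ("pi1" %in% stages) {
    needs("pi1", "cis")
    res$pi1 <- list()
    for (cell in unique(ct$cell_type)) {
      conds <- ct$condition[ct$cell_type == cell]
      disc <- res$cis[[conds[1]]]
      repl <- res$cis[[conds[2]]]$assoc
      eg <- disc$egenes[disc$egenes$is_egene, , drop = FALSE]
      if (nrow(eg) == 0L) next
      pairs <- data.frame(gene_id = eg$gene_id, snp_id = eg$top_snp)
      res$pi1[[cell]] <- tryCatch(replicationRate(pairs, repl),
                                  error = function(e) NULL)
    }
    counts$pi1 <- length(res$pi1)
  }
  manifest <- list(
    config = as.list(attributes(cfg)[slotNames("SimConfig")]),
    stages = stages, seed = cfg@seed, counts = counts,
    hashes = lapply(res[setdiff(names(res), "simulate")], md5OfObject))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(res$simulate)) {
      writeGenotypesVcf(res$simulate$panel, file.path(outDir, "genotypes.vcf"))
      writeStudyTsv(res$simulate$study, outDir)
      writeTruthJson(res$simulate$truth, file.path(outDir, "truth.json"))
      for (dis in names(res$simulate$gwas))
        writeGwasTsv(res$simulate$gwas[[dis]],
                     file.path(outDir, paste0("gwas_", dis, ".tsv")))
    }
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(results = res, manifest = manifest)
}
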