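## Full synthetic input bundle.
##
## Emulates the study design the pipeline is built for: one control sample
## (DMSO) and three treatments (AZD, RAP, AZD+RAP) sharing one genome and
## one control-arm truth, each treatment with its own set of planted
## differential regions drawn from a common gene-anchored pool so the
## treatment DMG sets partially overlap; plus a term map and median-effect
## dose-response tables with planted synergy.

#' Default true dose-response parameters of the bundle's agents
#'
#' Azacitidine: Dm 10 uM (its GI50), slope 1.8; AZD: Dm 1 uM; RAP: Dm 5 uM.
#' @return `data.frame(agent, m, Dm)`.
#' @export
bundleAgents <- function() {
  data.frame(agent = c("azacitidine", "AZD", "RAP"),
             m = c(1.8, 1.5, 1.3),
             Dm = c(10, 1, 5))
}

## internal: gene-anchored planted-region pool — one region of dmrLength
## centred on every k-th TSS so regions hit promoters and gene starts
.regionPool <- function(models, config, genome) {
  gn <- genes(models)
  K <- config@dmrCount
  if (length(gn) < K)
    stop("not enough genes (", length(gn), ") for a pool of ", K,
         " planted regions")
  idx <- unique(round(seq(1L, length(gn), length.out = K)))
  lens <- chromLengths(genome)
  half <- floor(config@dmrLength / 2)
  pool <- data.table(
    chrom = as.character(seqnames(gn))[idx],
    start = pmax(1L, as.integer(mcols(gn)$tss[idx] - half)),
    gene_id = mcols(gn)$gene_id[idx])
  pool[, end := pmin(as.integer(start + config@dmrLength - 1L),
                     as.integer(lens[chrom]))]
  pool[, `:=`(context = config@dmrContext, delta = config@dmrDelta)]
  pool[, .(chrom, start, end, context, delta, gene_id)]
}

#' Generate and write a complete synthetic input bundle
#'
#' Writes into `dir`: `genome.fa`, `genes.gff3`, one
#' `<sample>.CX_report.tsv` per sample, `truth_regions_<sample>.tsv`
#' ground-truth files, `terms.tsv` + `term_descriptions.tsv`, and
#' `dose_single.tsv` + `dose_combo.tsv`. Treatment region sets are slices
#' of a shared pool (AZD the first half, RAP a middle band, AZD+RAP from
#' the band's start to the end) so the three DMG sets overlap partially.
#'
#' @param config A [SimulationConfig-class].
#' @param dir Output directory (created if needed).
#' @param control Control sample name.
#' @param treatments Treatment sample names (region slices are assigned in
#'   this order).
#' @return Invisibly, a list with the in-memory objects: `genome`,
#'   `models`, `truthControl`, per-sample truths and methylomes, the region
#'   `pool` and per-treatment `regions`, `termMap`, `agents`, and `paths`.
#' @export
simulateMethylomeBundle <- function(config, dir, control = "DMSO",
                                    treatments = c("AZD", "RAP",
                                                   "AZD+RAP")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fn <- function(...) file.path(dir, paste0(...))
  safe <- function(s) gsub("[^A-Za-z0-9_.-]", "_", s)
  genome <- simulateGenome(config)
  models <- simulateGeneModels(genome)
  truthControl <- simulateTrueMethylome(genome, config)
  pool <- .regionPool(models, config, genome)
  K <- nrow(pool)
  slices <- list(seq_len(ceiling(K * 0.5)),
                 seq.int(max(1L, ceiling(K * 0.25)), ceiling(K * 0.85)),
                 seq.int(max(1L, ceiling(K * 0.25)), K))
  slices <- slices[seq_along(treatments)]
  names(slices) <- treatments
  paths <- c(genome = fn("genome.fa"), gff = fn("genes.gff3"),
             terms = fn("terms.tsv"),
             term_desc = fn("term_descriptions.tsv"),
             dose_single = fn("dose_single.tsv"),
             dose_combo = fn("dose_combo.tsv"))
  writeGenomeFasta(genome, paths[["genome"]])
  writeGeneModels(models, paths[["gff"]])
  truths <- list(); samples <- list(); regions <- list()
  allSamples <- c(control, treatments)
  for (s in allSamples) {
    if (s == control) {
      truths[[s]] <- truthControl
      regions[[s]] <- pool[0L]
    } else {
      regions[[s]] <- pool[slices[[s]]]
      truths[[s]] <- plantDMRs(truthControl, config,
                               regions = regions[[s]][, .(chrom, start, end,
                                                          context, delta)])
    }
    samples[[s]] <- simulateCounts(truths[[s]], config, s)
    cx <- fn(safe(s), ".CX_report.tsv")
    writeCXReport(samples[[s]], cx)
    paths[[paste0("cx_", s)]] <- cx
    tr <- fn("truth_regions_", safe(s), ".tsv")
    writeTsv(regions[[s]], tr)
    paths[[paste0("truth_", s)]] <- tr
  }
  targetGenes <- unique(unlist(lapply(treatments,
                                      function(s) regions[[s]]$gene_id)))
  termMap <- simulateTermMap(geneIds(models), targetGenes,
                             seed = config@seed)
  termMap$background <- geneIds(models)
  writeTsv(termMap$map, paths[["terms"]])
  writeTsv(termMap$descriptions, paths[["term_desc"]])
  agents <- bundleAgents()
  controlWeight <- 100
  cv <- 0.05
  singleRows <- list()
  for (i in seq_len(nrow(agents))) {
    ag <- agents$agent[i]
    doses <- agents$Dm[i] * c(0.25, 0.5, 1, 2, 4)
    for (rep_ in 1:3) {
      old <- .Random.seed_exists()
      set.seed(deriveSeed(config@seed, paste0("dose:", ag, ":", rep_)))
      dr <- simulateDoseResponse(agents$m[i], agents$Dm[i], doses, cv = cv)
      w0 <- controlWeight * stats::rlnorm(1L, -cv^2 / 2, cv)
      .restore_seed(old)
      singleRows[[paste(ag, rep_)]] <- rbind(
        data.table(agent = ag, dose_uM = 0, replicate = rep_,
                   fresh_weight_mg = w0),
        data.table(agent = ag, dose_uM = dr$dose, replicate = rep_,
                   fresh_weight_mg = controlWeight * (1 - dr$fa)))
    }
  }
  writeTsv(rbindlist(singleRows), paths[["dose_single"]])
  trueFit <- function(i) new("MedianEffectFit", agent = agents$agent[i],
                             m = agents$m[i], Dm = agents$Dm[i], r2 = 1,
                             n = 5L)
  combos <- data.table(agent1 = c("RAP", "AZD"), dose1_uM = c(5, 1),
                       agent2 = c("azacitidine", "azacitidine"),
                       dose2_uM = c(10, 10), ci_true = c(0.45, 0.8))
  comboRows <- list()
  for (i in seq_len(nrow(combos))) {
    f1 <- trueFit(match(combos$agent1[i], agents$agent))
    f2 <- trueFit(match(combos$agent2[i], agents$agent))
    for (rep_ in 1:3) {
      fa <- simulateComboResponse(
        f1, f2, combos$dose1_uM[i], combos$dose2_uM[i], combos$ci_true[i],
        cv = cv, seed = deriveSeed(config@seed,
                                   paste0("combo:", i, ":", rep_)))
      old <- .Random.seed_exists()
      set.seed(deriveSeed(config@seed, paste0("combo0:", i, ":", rep_)))
      w0 <- controlWeight * stats::rlnorm(1L, -cv^2 / 2, cv)
      .restore_seed(old)
      comboRows[[paste(i, rep_)]] <- rbind(
        data.table(agent1 = combos$agent1[i], dose1_uM = 0,
                   agent2 = combos$agent2[i], dose2_uM = 0,
                   replicate = rep_, fresh_weight_mg = w0),
        data.table(agent1 = combos$agent1[i], dose1_uM = combos$dose1_uM[i],
                   agent2 = combos$agent2[i], dose2_uM = combos$dose2_uM[i],
                   replicate = rep_,
                   fresh_weight_mg = controlWeight * (1 - fa)))
    }
  }
  writeTsv(rbindlist(comboRows), paths[["dose_combo"]])
  invisible(list(genome = genome, models = models,
                 truthControl = truthControl, truths = truths,
                 samples = samples, pool = pool, regions = regions,
                 termMap = termMap, agents = agents, combosTrue = combos,
                 control = control, treatments = treatments,
                 paths = paths))
}
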