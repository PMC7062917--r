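## Pipeline orchestration: simulate -> summarize -> profile -> dmr ->
## enrich -> synergy as one reproducible run. Every output under the run
## directory is written deterministically (sorted rows, fixed numeric
## formats, no timestamps), so two runs with the same configuration are
## byte-identical.

#' Build a run configuration
#'
#' @param outDir Output directory for the run.
#' @param seed Master seed.
#' @param simulation Named list of [SimulationConfig()] arguments (synthetic
#'   mode), or `NULL` to analyse existing inputs.
#' @param inputs Named list of input paths (`genome`, `gff`, per-sample CX
#'   reports under `cx`, `terms`, `dose_single`, `dose_combo`); filled in
#'   automatically in synthetic mode.
#' @param control Control sample name.
#' @param treatments Treatment sample names; each is contrasted against the
#'   control.
#' @param dmr Named list of [DmrParams()] arguments.
#' @param contexts Contexts tested for DMRs.
#' @return A `run_config` list.
#' @export
RunConfig <- function(outDir, seed = 1L, simulation = list(),
                      inputs = NULL, control = "DMSO",
                      treatments = c("AZD", "RAP", "AZD+RAP"),
                      dmr = list(), contexts = c("CG", "CHG", "CHH")) {
  structure(list(outDir = outDir, seed = as.integer(seed),
                 simulation = simulation, inputs = inputs,
                 control = as.character(control),
                 treatments = as.character(unlist(treatments)), dmr = dmr,
                 contexts = as.character(unlist(contexts))),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with the fields of [RunConfig()].
#' @return A `run_config` list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(RunConfig, y[intersect(names(y), names(formals(RunConfig)))])
}

## internal: realise the SimulationConfig from a config list
.asSimulationConfig <- function(cfg) {
  args <- cfg$simulation
  if (is.null(args)) args <- list()
  if (is.null(args$seed)) args$seed <- cfg$seed
  if (!is.null(args$baseLevels)) args$baseLevels <- unlist(args$baseLevels)
  do.call(SimulationConfig, args)
}

#' Run the full methylome pipeline
#'
#' Stages: (1) synthetic-input generation (synthetic mode) or input
#' loading; (2) per-sample non-conversion estimation, methylated-site
#' calling, context proportions, sliding-window and 10-kb-bin genome
#' summaries; (3) functional-element metaprofiles; (4) per-contrast,
#' per-context DMR calling with annotation and DMG collection; (5) DMG
#' Venn overlaps and Pearson-distance clustering; (6) term
#' over-representation per contrast; (7) median-effect fits and the Fa-CI
#' synergy curve. A JSON manifest records the effective configuration, a
#' configuration hash, the seed, the package version and per-stage row
#' counts. Any stage failure aborts with the stage name.
#'
#' @param config A `run_config` from [RunConfig()]/[readRunConfig()], or a
#'   path to a YAML file.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  allSamples <- c(config$control, config$treatments)

  ## stage: inputs
  synthetic <- is.null(config$inputs)
  bundle <- NULL
  if (synthetic) {
    simCfg <- .asSimulationConfig(config)
    bundle <- stage("simulate", simulateMethylomeBundle(
      simCfg, file.path(out, "inputs"), control = config$control,
      treatments = config$treatments))
    inputs <- as.list(bundle$paths)
    names(inputs) <- names(bundle$paths)
  } else {
    inputs <- config$inputs
  }
  missing <- setdiff(paste0("cx_", allSamples), names(inputs))
  if (length(missing))
    stop("contrast references sample(s) without CX input: ",
         paste(sub("^cx_", "", missing), collapse = ", "))

  genome <- stage("load", readGenomeFasta(
    inputs$genome, controlChrom = if (synthetic) simCfg@lambdaName
                                  else config$controlChrom %||% NA))
  models <- stage("load", readGeneModels(inputs$gff))
  methylomes <- stage("load", {
    ms <- lapply(allSamples, function(s)
      readCXReport(inputs[[paste0("cx_", s)]], sampleId = s,
                   genome = genome))
    stats::setNames(ms, allSamples)
  })
  counts$sites_per_sample <- vapply(methylomes,
                                    function(m) length(methSites(m)),
                                    numeric(1))

  ## stage: summarize
  sumDir <- file.path(out, "summaries")
  dir.create(sumDir, showWarnings = FALSE)
  lens <- chromLengths(genome)
  props <- list(); rates <- numeric()
  stage("summarize", for (s in allSamples) {
    m <- estimateNonconversion(methylomes[[s]], genome)
    methylomes[[s]] <- m
    rates[[s]] <- nonconversionRate(m)
    calls <- callMethylatedSites(m)
    pr <- contextProportions(calls, by = "both",
                             excludeChrom = controlChrom(genome))
    pr[, sample_id := s]
    props[[s]] <- pr
    wins <- rbindlist(lapply(c(VALID_CONTEXTS, "combined"), function(cx) {
      w <- slidingWindowML(m, 3000L, 600L, context = cx, chromLens = lens)
      w[, context := cx]
      w
    }))
    writeTsv(wins, file.path(sumDir, paste0(
      "windows_", gsub("[^A-Za-z0-9_.-]", "_", s), ".tsv")))
    bins <- binProfile(m, 10000L, chromLens = lens)
    writeTsv(bins, file.path(sumDir, paste0(
      "bins10kb_", gsub("[^A-Za-z0-9_.-]", "_", s), ".tsv")))
  })
  propTab <- rbindlist(props)
  writeTsv(propTab, file.path(sumDir, "context_proportions.tsv"))
  writeTsv(data.table(sample_id = names(rates),
                      nonconversion_rate = unname(rates)),
           file.path(sumDir, "nonconversion_rates.tsv"))
  counts$context_proportion_rows <- nrow(propTab)

  ## stage: profile
  profDir <- file.path(out, "profiles")
  dir.create(profDir, showWarnings = FALSE)
  elements <- stage("profile", deriveElements(models, genome))
  profTab <- stage("profile", rbindlist(lapply(allSamples, function(s) {
    rbindlist(lapply(ELEMENT_TYPES, function(et) {
      rbindlist(lapply(VALID_CONTEXTS, function(cx) {
        pr <- metaProfile(methylomes[[s]], elements, et, context = cx)
        pr[, `:=`(sample_id = s, element_type = et, context = cx)]
        pr
      }))
    }))
  })))
  writeTsv(profTab, file.path(profDir, "metaprofiles.tsv"))
  counts$metaprofile_rows <- nrow(profTab)

  ## stage: dmr
  dmrDir <- file.path(out, "dmr")
  dir.create(dmrDir, showWarnings = FALSE)
  params <- do.call(DmrParams, config$dmr)
  dmgSets <- list(); dmrTabs <- list(); dmgTabs <- list()
  stage("dmr", for (tr in config$treatments) {
    dmrs <- rbindlist(lapply(config$contexts, function(cx)
      callDMRs(methylomes[[tr]], methylomes[[config$control]], params,
               context = cx, chromLens = lens)))
    dmrs <- annotateDMRs(dmrs, elements)
    setorder(dmrs, chrom, start, end, context)
    safeTr <- gsub("[^A-Za-z0-9_.-]", "_", tr)
    writeDmrOutputs(dmrs, file.path(dmrDir, paste0("dmrs_", safeTr)))
    dmgs <- collectDMGs(dmrs, methylomes[[tr]], methylomes[[config$control]],
                        params)
    writeTsv(dmgs, file.path(dmrDir, paste0("dmgs_", safeTr, ".tsv")))
    dmrTabs[[tr]] <- dmrs
    dmgTabs[[tr]] <- dmgs
    dmgSets[[tr]] <- dmgs$gene_id
  })
  counts$dmrs_per_contrast <- vapply(dmrTabs, nrow, numeric(1))
  counts$dmgs_per_contrast <- vapply(dmgTabs, nrow, numeric(1))

  ## stage: venn + clustering
  stage("venn", if (length(dmgSets) >= 2L) {
    venn <- vennOverlap(dmgSets[seq_len(min(3L, length(dmgSets)))])
    writeTsv(venn, file.path(dmrDir, "dmg_venn.tsv"))
    counts$venn_regions <- nrow(venn)
  })
  stage("cluster", {
    allDmg <- sort(unique(unlist(dmgSets)))
    newick <- ""
    if (length(allDmg) >= 2L) {
      longs <- rbindlist(lapply(names(dmrTabs), function(tr) {
        d <- dmrTabs[[tr]][gene_ids != ""]
        if (nrow(d) == 0L) return(NULL)
        d[, .(gene_id = strsplit(gene_ids, ",", fixed = TRUE)[[1L]]),
          by = .(chrom, start, end, context)]
      }))
      longs <- unique(longs)
      siteTabs <- lapply(methylomes, function(m) {
        st <- .siteTable(m)
        st[M + U >= params@minSiteCoverage]
      })
      mat <- matrix(NA_real_, length(allDmg), length(allSamples),
                    dimnames = list(allDmg, allSamples))
      for (g in allDmg) {
        regs <- longs[gene_id == g]
        for (s in allSamples) {
          st <- siteTabs[[s]]
          sel <- unique(rbindlist(lapply(seq_len(nrow(regs)), function(i)
            st[chrom == regs$chrom[i] & pos >= regs$start[i] &
                 pos <= regs$end[i] & context == regs$context[i]])))
          mat[g, s] <- if (nrow(sel) && sum(sel$M + sel$U) > 0)
            sum(sel$M) / sum(sel$M + sel$U) else NA_real_
        }
      }
      keep <- stats::complete.cases(mat)
      mat <- mat[keep, , drop = FALSE]
      if (nrow(mat) >= 2L) {
        cl <- suppressWarnings(clusterDMGs(mat))
        newick <- cl$newick
      }
    }
    writeLines(newick, file.path(dmrDir, "dmg_dendrogram.nwk"))
  })

  ## stage: enrichment
  enrDir <- file.path(out, "enrichment")
  dir.create(enrDir, showWarnings = FALSE)
  stage("enrich", {
    termMap <- readTermMap(inputs$terms, inputs$term_desc,
                           background = geneIds(models))
    for (tr in names(dmgSets)) {
      hits <- intersect(dmgSets[[tr]], termMap$background)
      enr <- enrichTerms(hits, termMap)
      writeTsv(enr, file.path(enrDir, paste0(
        "enrichment_", gsub("[^A-Za-z0-9_.-]", "_", tr), ".tsv")))
    }
  })

  ## stage: synergy
  synDir <- file.path(out, "synergy")
  dir.create(synDir, showWarnings = FALSE)
  stage("synergy", {
    single <- readDoseTable(inputs$dose_single)
    fits <- lapply(split(single, single$agent), function(d)
      fitMedianEffect(d$dose, d$fa, agent = d$agent[1L]))
    fitTab <- rbindlist(lapply(fits, function(f)
      data.table(agent = f@agent, m = f@m, Dm_uM = f@Dm, r2 = f@r2,
                 n = f@n)))
    setorder(fitTab, agent)
    writeTsv(fitTab, file.path(synDir, "median_effect_fits.tsv"))
    combo <- readTsv(inputs$dose_combo)
    data.table::setnames(combo, c("agent1", "dose1_uM", "agent2",
                                  "dose2_uM", "replicate",
                                  "fresh_weight_mg"))
    combo[, pair := paste(agent1, agent2, sep = "+")]
    rows <- list()
    for (pr in sort(unique(combo$pair))) {
      d <- combo[pair == pr]
      ctrl <- d[dose1_uM == 0 & dose2_uM == 0, mean(fresh_weight_mg)]
      obs <- d[dose1_uM > 0 | dose2_uM > 0,
               .(w = mean(fresh_weight_mg)), by = .(agent1, dose1_uM,
                                                    agent2, dose2_uM)]
      for (i in seq_len(nrow(obs))) {
        fa <- faFromFreshWeight(obs$w[i], ctrl)
        ci <- combinationIndex(obs$dose1_uM[i], obs$dose2_uM[i], fa,
                               fits[[obs$agent1[i]]], fits[[obs$agent2[i]]])
        rows[[paste(pr, i)]] <- data.table(
          pair = pr, d1_uM = ci$d1, d2_uM = ci$d2, fa = ci$fa, ci = ci$ci,
          verdict = ci$verdict)
      }
    }
    faci <- rbindlist(rows)
    setorder(faci, pair, fa)
    writeTsv(faci, file.path(synDir, "fa_ci.tsv"))
    counts$ci_rows <- nrow(faci)
  })

  ## manifest
  effective <- unclass(config)
  effective$inputs <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("methylscape")),
    seed = config$seed,
    config = effective,
    config_hash = rlang::hash(effective),
    nonconversion_rates = as.list(rates),
    counts = lapply(counts, as.list))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
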