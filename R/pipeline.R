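# Orchestration: YAML configuration with strict validation, and a staged
# runner chaining simulate -> prep -> module -> cluster -> enrich, plus the
# damid and imaging branches. All stage hand-off is via files in the output
# directory; the fully resolved configuration is written beside the
# outputs, so two runs with identical config and inputs are reproducible.

.configDefaults <- function() list(
  seed = 1L,
  outdir = "adhesomics_results",
  stages = c("simulate", "prep", "module", "cluster"),
  inputs = list(abundance = NULL, groups = NULL, edges = NULL,
                genome = NULL, fusion_bed = NULL, control_bed = NULL,
                gmt = NULL),
  simulate = list(n_proteins = 2000L, n_per_group = 3L, frac_diff = 0.1,
                  effect_log2fc = 2, noise_sd = 0.3, mnar_quantile = 0.25,
                  n_nodes = 200L, mean_degree = 4, module_size = 20L,
                  signal_a = 0.2,
                  chrom_len = 2e5, gatc_spacing = 200L, enrichment = 4,
                  reads_per_condition = 2e5),
  prep = list(min_present = 2L, fold = 2, q = 0.05, donors = 5L,
              iters = 10L, input_scale = "log2"),
  module = list(fdr = 0.05, max_exact_nodes = 20L, default_p = 0.5),
  cluster = list(method = "modularity",
                 gamma_grid = exp(seq(log(0.01), log(2),
                                      length.out = 25))),
  enrich = list(q = 0.05, min_ratio = 1, top_k = 2L),
  damid = list(flank = 250L, eps = 0.5, min_quantile = 0.75, step = 5e-4,
               iterations = 15L, fdr = 0.05, min_run = 5L),
  imaging = list(top = 1500))

.mergeConfig <- function(defaults, user, path = character(),
                         errors = new.env()) {
  for (k in names(user)) {
    full <- paste(c(path, k), collapse = ".")
    if (!k %in% names(defaults)) {
      errors$msgs <- c(errors$msgs, sprintf("unknown key '%s'", full))
      next
    }
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) {
        errors$msgs <- c(errors$msgs,
                         sprintf("'%s' must be a mapping", full))
      } else {
        defaults[[k]] <- .mergeConfig(defaults[[k]], user[[k]],
                                      c(path, k), errors)
      }
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate (and resolve) a pipeline configuration
#'
#' Merges a user configuration (YAML file path or list) over the defaults
#' — the defaults are the study's parameter choices: two-fold / q < 0.05
#' differential gates, 5 percent score-calibration FDR, 250-bp window
#' flank, peak quantile 0.75 with step 0.0005 and 15 iterations — rejecting
#' unknown keys and enforcing cross-field constraints. All violations are
#' reported together, not just the first.
#'
#' @param config Path to a YAML file, or a nested list.
#' @return The fully resolved configuration list (invisibly a valid one);
#'   errors with the full violation report otherwise.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  errs <- new.env(); errs$msgs <- character()
  cfg <- .mergeConfig(.configDefaults(), config, errors = errs)
  chk <- function(cond, msg) if (!isTRUE(cond))
    errs$msgs <- c(errs$msgs, msg)
  known <- c("simulate", "prep", "module", "cluster", "enrich", "damid",
             "imaging")
  chk(all(cfg$stages %in% known),
      paste("unknown stage(s):",
            paste(setdiff(cfg$stages, known), collapse = ", ")))
  chk(cfg$prep$fold >= 1, "prep.fold must be >= 1")
  chk(cfg$prep$q > 0 && cfg$prep$q < 1, "prep.q must lie in (0, 1)")
  chk(cfg$prep$donors >= 1, "prep.donors must be >= 1")
  chk(cfg$module$fdr > 0 && cfg$module$fdr < 1,
      "module.fdr must lie in (0, 1)")
  chk(cfg$cluster$method %in% c("modularity", "cpm"),
      "cluster.method must be 'modularity' or 'cpm'")
  chk(cfg$damid$min_quantile < 1, "damid.min_quantile must be < 1")
  chk(cfg$damid$step > 0, "damid.step must be positive")
  chk(cfg$damid$iterations >= 1, "damid.iterations must be >= 1")
  chk(cfg$imaging$top > 0, "imaging.top must be positive")
  if (length(errs$msgs))
    stop("invalid configuration:\n  - ",
         paste(errs$msgs, collapse = "\n  - "), call. = FALSE)
  cfg
}

#' Run the staged analysis pipeline
#'
#' Executes the requested stage chain, writing per-stage outputs, a log and
#' a machine-readable `summary.json` into `config$outdir`. With the
#' `simulate` stage enabled the pipeline is self-contained (synthetic
#' inputs with recorded ground truth); otherwise file inputs under
#' `config$inputs` are used. Stages depending on an absent upstream
#' artifact fail with an error naming it.
#'
#' @param config Path to YAML or nested list (see [validateConfig()]).
#' @return Invisibly, the summary list (also written as JSON).
#' @export
runPipeline <- function(config = list()) {
  cfg <- validateConfig(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(cfg$outdir, "pipeline.log")
  logLine <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = logFile, append = TRUE, sep = "")
    message(msg)
  }
  logLine("adhesomics ", as.character(utils::packageVersion("adhesomics")),
          " | R ", getRversion(), " | seed ", cfg$seed)
  yaml::write_yaml(cfg, file.path(cfg$outdir, "config.resolved.yaml"))
  summary <- list(seed = cfg$seed, stages = as.list(cfg$stages))

  se <- NULL; edges <- NULL; lfqTruth <- NULL; netTruth <- NULL
  damidSim <- NULL

  if ("simulate" %in% cfg$stages) {
    sc <- cfg$simulate
    lfq <- simulateLfq(sc$n_proteins, sc$n_per_group, sc$frac_diff,
                       sc$effect_log2fc, sc$noise_sd, sc$mnar_quantile,
                       seed = cfg$seed)
    se <- lfq$se; lfqTruth <- lfq$truth
    net <- simulatePpiNetwork(sc$n_nodes, sc$mean_degree, sc$module_size,
                              seed = cfg$seed + 1L)
    # graph the simulated proteome: network nodes are the first n_nodes
    # protein ids, so abundance p-values attach to graph vertices
    if (sc$n_nodes > sc$n_proteins)
      stop("simulate.n_nodes must not exceed simulate.n_proteins")
    prot <- rownames(lfq$se)[seq_len(sc$n_nodes)]
    edges <- net$edges
    edges[] <- prot[match(net$edges, net$nodes)]
    netTruth <- net$truth
    netTruth$plantedMembers <- prot[match(netTruth$plantedMembers,
                                          net$nodes)]
    if ("damid" %in% cfg$stages) {
      # two planted LADs, each 5% of the chromosome, at fixed fractions
      lads <- data.frame(chrom = "chrS",
                         start = round(c(0.24, 0.60) * sc$chrom_len),
                         end = round(c(0.29, 0.65) * sc$chrom_len))
      damidSim <- simulateDamid(sc$chrom_len, sc$gatc_spacing, lads = lads,
                                enrichment = sc$enrichment,
                                readsPerCondition = sc$reads_per_condition,
                                seed = cfg$seed + 2L)
    }
    writeAbundanceTsv(se, file.path(cfg$outdir, "abundance.tsv"),
                      "simulate", sc)
    jsonlite::write_json(
      list(differentialIds = lfqTruth$differentialIds,
           plantedMembers = netTruth$plantedMembers),
      file.path(cfg$outdir, "truth.json"))
    logLine("simulate: ", nrow(se), " proteins, ",
            nrow(edges), " network edges")
  } else {
    if (!is.null(cfg$inputs$abundance)) {
      if (is.null(cfg$inputs$groups))
        stop("inputs.groups required with inputs.abundance")
      se <- readAbundanceTsv(cfg$inputs$abundance,
                             unlist(cfg$inputs$groups))
    }
    if (!is.null(cfg$inputs$edges)) edges <- readEdgeList(cfg$inputs$edges)
  }

  diffTab <- NULL
  if ("prep" %in% cfg$stages) {
    if (is.null(se)) stop("prep stage requires an abundance matrix ",
                          "(simulate stage or inputs.abundance)")
    pc <- cfg$prep
    if (identical(pc$input_scale, "linear"))
      SummarizedExperiment::assay(se, 1L) <-
        log2(SummarizedExperiment::assay(se, 1L))
    se <- filterReplication(se, pc$min_present)
    se <- rlrNormalize(se)
    se <- imputeMnarMin(se)
    se <- imputePmm(se, donors = pc$donors, iters = pc$iters,
                    seed = cfg$seed)
    diffTab <- differentialAbundance(se, fold = pc$fold, qThr = pc$q)
    .writeTable(diffTab, file.path(cfg$outdir, "differential.tsv"),
                "prep", pc)
    writeAbundanceTsv(se, file.path(cfg$outdir, "abundance.imputed.tsv"),
                      "prep", pc)
    summary$prep <- list(n_proteins = nrow(diffTab),
                         n_significant = sum(diffTab$significant))
    logLine("prep: ", nrow(diffTab), " proteins tested, ",
            sum(diffTab$significant), " significant")
  }

  module <- NULL
  if ("module" %in% cfg$stages) {
    if (is.null(edges)) stop("module stage requires a network ",
                             "(simulate stage or inputs.edges)")
    if (is.null(diffTab)) stop("module stage requires the prep stage's ",
                               "differential table")
    mc <- cfg$module
    pv <- setNames(diffTab$p, diffTab$id)
    fit <- fitBum(pv)
    scores <- scoreNodes(fit, pv, fdr = mc$fdr,
                         nodes = sort(unique(as.vector(edges))),
                         defaultP = mc$default_p)
    net <- scoredNetwork(edges, scores)
    module <- if (igraph::vcount(net@graph) <= mc$max_exact_nodes)
      solveMwcsExact(net, mc$max_exact_nodes) else solveMwcsHeuristic(net)
    .writeTable(data.frame(node = moduleMembers(module),
                           score = unname(scores[moduleMembers(module)])),
                file.path(cfg$outdir, "module.tsv"), "module", mc)
    writeModuleSif(module, file.path(cfg$outdir, "module.sif"))
    summary$module <- list(n_members = length(moduleMembers(module)),
                           total_score = moduleScore(module),
                           bum_lambda = fit@lambda, bum_a = fit@a)
    logLine("module: ", length(moduleMembers(module)),
            " members, score ", format(moduleScore(module), digits = 5))
  }

  part <- NULL
  if ("cluster" %in% cfg$stages) {
    if (is.null(module)) stop("cluster stage requires the module stage")
    if (is.null(se)) stop("cluster stage requires abundance profiles")
    cc <- cfg$cluster
    g0 <- igraph::simplify(igraph::graph_from_edgelist(edges,
                                                       directed = FALSE))
    sub <- igraph::induced_subgraph(
      g0, intersect(moduleMembers(module), igraph::V(g0)$name))
    part <- if (igraph::ecount(sub) == 0L) {
      # degenerate module (single node or no internal edges)
      new("Partition",
          membership = setNames(rep(1L, igraph::vcount(sub)),
                                igraph::V(sub)$name),
          quality = 0, qualityKind = "modularity_Q", gamma = NA_real_)
    } else {
      wdf <- abundanceEdgeWeights(se, igraph::as_edgelist(sub),
                                  mode = cc$method)
      gw <- igraph::set_edge_attr(sub, "weight", value = wdf$weight)
      if (cc$method == "modularity") louvainModularity(gw, seed = cfg$seed)
      else scanGamma(gw, grid = unlist(cc$gamma_grid), seed = cfg$seed)
    }
    .writeTable(data.frame(node = names(communityMembership(part)),
                           community = unname(communityMembership(part))),
                file.path(cfg$outdir, "partition.tsv"), "cluster", cc)
    jsonlite::write_json(
      list(kind = part@qualityKind, value = part@quality,
           gamma = if (is.na(part@gamma)) NULL else part@gamma),
      file.path(cfg$outdir, "partition.quality.json"), auto_unbox = TRUE)
    hubs <- classifyHubs(sub, part)
    .writeTable(hubs, file.path(cfg$outdir, "hubs.tsv"), "cluster", cc)
    summary$cluster <- list(
      n_communities = length(unique(communityMembership(part))),
      quality = part@quality, kind = part@qualityKind)
    logLine("cluster: ", summary$cluster$n_communities, " communities (",
            part@qualityKind, " = ", format(part@quality, digits = 5), ")")
  }

  if ("enrich" %in% cfg$stages) {
    if (is.null(part)) stop("enrich stage requires the cluster stage")
    if (is.null(cfg$inputs$gmt)) stop("enrich stage requires inputs.gmt")
    gsc <- readGmt(cfg$inputs$gmt)
    ec <- cfg$enrich
    universe <- sort(unique(as.vector(edges)))
    ann <- annotateClusters(part, universe, gsc, topK = ec$top_k,
                            qThr = ec$q)
    jsonlite::write_json(ann, file.path(cfg$outdir, "annotations.json"))
    summary$enrich <- list(
      n_annotated = sum(vapply(ann, function(x)
        !identical(x, "unannotated"), logical(1))))
    logLine("enrich: ", summary$enrich$n_annotated,
            " communities annotated")
  }

  if ("damid" %in% cfg$stages) {
    dc <- cfg$damid
    if (!is.null(damidSim)) {
      genome <- damidSim$genome
      fusion <- damidSim$fusionReads
      control <- damidSim$controlReads
    } else {
      need <- c("genome", "fusion_bed", "control_bed")
      miss <- need[vapply(cfg$inputs[need], is.null, logical(1))]
      if (length(miss))
        stop("damid stage missing input(s): ", paste(miss, collapse = ", "))
      genome <- Biostrings::readDNAStringSet(cfg$inputs$genome)
      fusion <- .readBed3(cfg$inputs$fusion_bed)
      control <- .readBed3(cfg$inputs$control_bed)
    }
    track <- buildGatcMap(genome, flank = dc$flank)
    track <- countReads(track, fusion, "fusion")
    track <- countReads(track, control, "control")
    track <- normalizeRpm(track)
    track <- logRatio(track, eps = dc$eps)
    peaks <- callPeaks(track, minQuantile = dc$min_quantile,
                       step = dc$step, iterations = dc$iterations,
                       fdrThr = dc$fdr, minRun = dc$min_run,
                       seed = cfg$seed)
    writeBedGraph(track, file.path(cfg$outdir, "log2ratio.bedgraph"))
    write.table(peaks, file.path(cfg$outdir, "peaks.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    summary$damid <- list(n_windows = length(gatcWindows(track)),
                          n_peaks = nrow(peaks))
    logLine("damid: ", length(gatcWindows(track)), " windows, ",
            nrow(peaks), " peaks")
  }

  if ("imaging" %in% cfg$stages) {
    vp <- simulateVoxelPair(seed = cfg$seed)
    mm <- mandersCooccurrence(vp$a, vp$b)
    summary$imaging <- list(Ma = unname(mm["Ma"]), Mb = unname(mm["Mb"]))
    logLine("imaging: Ma = ", format(mm["Ma"], digits = 4),
            ", Mb = ", format(mm["Mb"], digits = 4))
  }

  jsonlite::write_json(summary, file.path(cfg$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(summary)
}
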