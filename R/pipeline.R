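# One-shot orchestration: simulate/load -> infer-scc -> de -> consistency ->
# group-structure -> survival, with a JSON run manifest, parameter digests
# and digest-based resume of completed stages.

.fmtNum <- function(x) {
  if (is.double(x)) sprintf("%.10g", x) else x
}

# Deterministic TSV writer: doubles formatted to 10 significant digits so
# repeat runs are byte-identical.
.writeTSV <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) df[[j]] <- .fmtNum(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.md5Of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, force = TRUE,
                              digits = NA, null = "null"), f)
  unname(tools::md5sum(f))
}

#' Validate and normalize a pipeline configuration
#'
#' A configuration is a named list (or a YAML file path) with optional
#' sections `sim`, `thresholds`, `panel`, `de`, `consistency`,
#' `group_structure`, `survival`, `input`, plus `seed`.  Every threshold is
#' validated here (S4 validity of the parameter classes), before any stage
#' runs, and echoed into the run manifest.
#'
#' @param config named list or path to a YAML file.
#' @return normalized config list with instantiated parameter objects.
#' @export
pipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  get <- function(name, default = list()) config[[name]] %||% default
  seed <- as.integer(get("seed", 1L))
  sim <- do.call(simConfig, c(list(seed = seed), get("sim")))
  thresholds <- do.call(ExpressionThresholds, get("thresholds"))
  panel <- do.call(MarkerPanel, get("panel"))
  de <- do.call(DEConfig, get("de"))
  consistency <- do.call(ConsistencyCriteria, get("consistency"))
  gs <- utils::modifyList(list(n_top = 3000L, n_components = 2L,
                               scale_genes = TRUE), get("group_structure"))
  surv <- utils::modifyList(list(min_group_size = 2L), get("survival"))
  input <- get("input", NULL)
  if (!is.null(input)) {
    stopifnot(!is.null(input$expression), !is.null(input$sample_sheet))
    for (f in c(input$expression, input$sample_sheet))
      if (!file.exists(f)) stop("pipelineConfig: input file not found: ", f,
                                call. = FALSE)
  }
  list(seed = seed, sim = sim, thresholds = thresholds, panel = panel,
       de = de, consistency = consistency, group_structure = gs,
       survival = surv, input = input)
}

.paramsAsList <- function(obj) {
  if (isVirtualClass(class(obj)) || !isS4(obj)) return(unclass(obj))
  sn <- slotNames(obj)
  setNames(lapply(sn, function(s) slot(obj, s)), sn)
}

#' Run the full SCC pipeline
#'
#' Executes the stages in dependency order, writing each stage's tables under
#' `out_dir` and a `manifest.json` recording parameters, stage digests and
#' output checksums.  When a stage's outputs already exist and its recorded
#' parameter digest matches, the stage is skipped (digest-based resume); a
#' stage failure aborts with the stage name, preserving completed outputs.
#'
#' @param config list or YAML path (see [pipelineConfig()]).
#' @param out_dir output directory, created if needed.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config = list(), out_dir) {
  cfg <- pipelineConfig(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else list(stages = list())
  params_echo <- list(seed = cfg$seed,
                      thresholds = .paramsAsList(cfg$thresholds),
                      panel = .paramsAsList(cfg$panel),
                      de = .paramsAsList(cfg$de),
                      consistency = .paramsAsList(cfg$consistency),
                      group_structure = cfg$group_structure,
                      survival = cfg$survival,
                      sim = unclass(cfg$sim))
  manifest$parameters <- params_echo

  state <- new.env(parent = emptyenv())

  run_stage <- function(name, param_obj, outputs, compute) {
    digest <- .md5Of(list(name = name, params = param_obj, seed = cfg$seed))
    paths <- file.path(out_dir, outputs)
    prior <- manifest$stages[[name]]
    if (!is.null(prior) && identical(prior$digest, digest) &&
        all(file.exists(paths))) {
      message("runPipeline: stage '", name, "' up to date; skipped")
      return(invisible(FALSE))
    }
    t0 <- Sys.time()
    ok <- tryCatch({ compute(paths); TRUE }, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      digest = digest, outputs = as.list(setNames(
        unname(tools::md5sum(paths)), outputs)),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, force = TRUE)
    invisible(TRUE)
  }

  # --- stage: cohort (simulate or load) ----------------------------------
  run_stage("cohort", if (is.null(cfg$input)) unclass(cfg$sim) else cfg$input,
            c("expression.tsv", "samples.tsv"), function(paths) {
    if (is.null(cfg$input)) {
      sim <- simulateCohort(cfg$sim)
      state$se <- sim$se; state$truth <- sim$truth
      jsonlite::write_json(list(scc = sim$truth$scc, de = sim$truth$de,
                                groups = sim$truth$groups),
                           file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
    } else {
      se <- readExpression(cfg$input$expression)
      ann <- readSampleSheet(cfg$input$sample_sheet)
      state$se <- alignSamples(se, ann)
    }
    writeExpression(state$se, paths[[1L]])
    .writeTSV(as.data.frame(colData(state$se)), paths[[2L]])
  })
  if (is.null(state$se)) {   # stage skipped on resume: reload
    se <- readExpression(file.path(out_dir, "expression.tsv"))
    ann <- readSampleSheet(file.path(out_dir, "samples.tsv"))
    state$se <- alignSamples(se, ann)
  }

  # --- stage: infer-scc ---------------------------------------------------
  run_stage("infer_scc", list(.paramsAsList(cfg$panel),
                              .paramsAsList(cfg$thresholds)),
            c("calls.tsv", "proportions.tsv", "low_signal_tissues.tsv"),
            function(paths) {
    batch <- inferSCCBatch(state$se, cfg$panel, cfg$thresholds)
    state$calls <- batch$calls
    low <- withCallingHandlers(
      flagLowSignalTissues(state$se, cfg$panel, cfg$thresholds),
      warning = function(w) invokeRestart("muffleWarning"))
    .writeTSV(as.data.frame(batch$calls), paths[[1L]])
    .writeTSV(batch$proportions, paths[[2L]])
    .writeTSV(low$medians, paths[[3L]])
  })
  if (is.null(state$calls))
    state$calls <- as(utils::read.delim(file.path(out_dir, "calls.tsv"),
                                        stringsAsFactors = FALSE), "DataFrame")

  contrasts <- list(
    lox = list(g1 = "XaXi", g2 = "X0_LOX", s1 = "female", s2 = "female"),
    xaxa = list(g1 = "XaXi", g2 = "XaXa", s1 = "female", s2 = "female"),
    loy = list(g1 = "XY", g2 = "X0_LOY", s1 = "male", s2 = "male"),
    sex = list(g1 = "XY", g2 = "XaXi", s1 = "male", s2 = "female"))

  # --- stage: de ----------------------------------------------------------
  de_dir <- file.path(out_dir, "de")
  run_stage("de", .paramsAsList(cfg$de), "de/de_index.tsv", function(paths) {
    dir.create(de_dir, showWarnings = FALSE)
    index <- list()
    state$de <- list()
    for (cn in names(contrasts)) {
      ct <- contrasts[[cn]]
      tabs <- fitDEPerTissue(state$se, state$calls, ct$g1, ct$g2,
                             ct$s1, ct$s2, cfg$de)
      state$de[[cn]] <- tabs
      for (tis in names(tabs)) {
        f <- paste0(cn, "_", tis, ".tsv")
        .writeTSV(tabs[[tis]], file.path(de_dir, f))
        index[[length(index) + 1L]] <- data.frame(
          contrast = cn, tissue = tis, file = f, stringsAsFactors = FALSE)
      }
    }
    .writeTSV(do.call(rbind, index), paths[[1L]])
  })
  if (is.null(state$de)) {
    idx <- utils::read.delim(file.path(out_dir, "de", "de_index.tsv"),
                             stringsAsFactors = FALSE)
    state$de <- lapply(split(idx, idx$contrast), function(d)
      setNames(lapply(file.path(de_dir, d$file), utils::read.delim,
                      stringsAsFactors = FALSE), d$tissue))
    state$de <- state$de[intersect(names(contrasts), names(state$de))]
  }

  # --- stage: consistency -------------------------------------------------
  run_stage("consistency", .paramsAsList(cfg$consistency),
            c("profiles.tsv", "profile_relations.tsv", "profile_overlaps.tsv"),
            function(paths) {
    profs <- list()
    for (cn in names(state$de)) {
      if (!length(state$de[[cn]])) next
      profs[[cn]] <- buildConsistentProfile(state$de[[cn]], cfg$consistency,
                                            contrast = cn)
    }
    state$profiles <- profs
    supp <- do.call(rbind, lapply(names(profs), function(cn) {
      s <- profs[[cn]]@support
      if (nrow(s)) cbind(contrast = cn, s) else NULL
    }))
    .writeTSV(supp %||% data.frame(contrast = character(), gene = character()),
              paths[[1L]])
    if (length(profs) >= 2L) {
      .writeTSV(profileSetRelations(lapply(profs, profileGenes)), paths[[2L]])
      pairs <- utils::combn(names(profs), 2L)
      ov <- lapply(seq_len(ncol(pairs)), function(i) {
        a <- profs[[pairs[1L, i]]]; b <- profs[[pairs[2L, i]]]
        # universe: genes tested in every tissue of both contrasts
        universe <- Reduce(intersect, lapply(state$de[c(pairs[1L, i], pairs[2L, i])],
                                             function(tabs) Reduce(intersect,
                                               lapply(tabs, `[[`, "gene"))))
        h <- hypergeometricOverlap(intersect(profileGenes(a), universe),
                                   intersect(profileGenes(b), universe),
                                   universe)
        data.frame(profileA = pairs[1L, i], profileB = pairs[2L, i],
                   k = h$k, expected = h$expected, p = h$p,
                   universe = length(universe), stringsAsFactors = FALSE)
      })
      .writeTSV(do.call(rbind, ov), paths[[3L]])
    } else {
      .writeTSV(data.frame(), paths[[2L]]); .writeTSV(data.frame(), paths[[3L]])
    }
  })

  # --- stage: group structure --------------------------------------------
  run_stage("group_structure", cfg$group_structure,
            c("plsda_scores.tsv", "plsda_centroids.tsv", "anova.tsv",
              "convergence.tsv"), function(paths) {
    grp <- sccGroup(state$calls)
    keep <- !is.na(grp) & grp %in% groupStructureGroups()
    tpm <- assay(state$se, "tpm")[, keep, drop = FALSE]
    chrom <- rowData(state$se)$chromosome
    av <- anovaPerGene(tpm, grp[keep], pseudocount = cfg$de@pseudocount)
    rows <- list(); conv <- list()
    for (autosomes_only in c(FALSE, TRUE)) {
      top <- selectTopGenes(av, cfg$group_structure$n_top,
                            exclude_sex_chromosomes = autosomes_only,
                            chromosome = chrom)
      proj <- plsdaProject(tpm[match(top, rownames(tpm)), , drop = FALSE],
                           grp[keep],
                           n_components = cfg$group_structure$n_components,
                           scale_genes = cfg$group_structure$scale_genes,
                           pseudocount = cfg$de@pseudocount)
      tag <- if (autosomes_only) "autosomal" else "all_genes"
      rows[[tag]] <- data.frame(gene_set = tag,
                                sample_id = rownames(plsScores(proj)),
                                group = proj@groups,
                                comp1 = plsScores(proj)[, 1L],
                                comp2 = plsScores(proj)[, 2L],
                                stringsAsFactors = FALSE)
      cen <- plsCentroids(proj)
      conv[[tag]] <- data.frame(gene_set = tag, group = rownames(cen),
                                comp1 = cen[, 1L], comp2 = cen[, 2L],
                                r = x0Convergence(proj),
                                stringsAsFactors = FALSE)
    }
    .writeTSV(do.call(rbind, rows), paths[[1L]])
    .writeTSV(do.call(rbind, conv), paths[[2L]])
    .writeTSV(av, paths[[3L]])
    .writeTSV(unique(do.call(rbind, conv)[, c("gene_set", "r")]), paths[[4L]])
  })

  # --- stage: survival ----------------------------------------------------
  run_stage("survival", cfg$survival,
            c("km_curves.tsv", "survival_medians.tsv", "logrank_global.tsv",
              "logrank_pairwise.tsv"), function(paths) {
    ann <- colData(state$se)
    sv <- survivalBySCC(state$calls, ann,
                        min_group_size = cfg$survival$min_group_size)
    km <- do.call(rbind, lapply(names(sv$curves), function(g) {
      cu <- sv$curves[[g]]
      data.frame(group = g, time = cu@time, surv = cu@surv,
                 n_risk = cu@n_risk, n_event = cu@n_event,
                 n_censor = cu@n_censor, stringsAsFactors = FALSE)
    }))
    .writeTSV(km, paths[[1L]])
    .writeTSV(sv$medians, paths[[2L]])
    .writeTSV(data.frame(chisq = sv$global$chisq, df = sv$global$df,
                         p = sv$global$p), paths[[3L]])
    .writeTSV(sv$pairwise, paths[[4L]])
  })

  invisible(jsonlite::read_json(manifest_path))
}
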