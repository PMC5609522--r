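# End-to-end orchestration: screen -> profile -> classify -> substrate ->
# genome context -> expression, with a machine-readable run manifest.

#' Default pipeline configuration
#'
#' Every threshold has a default; anything not supplied falls back to the
#' packaged reference data. The configuration round-trips through JSON.
#'
#' @param proteome path to a protein FASTA (or named sequences); required at
#'   run time.
#' @param refs reference panel sequences; defaults to the packaged subgroup
#'   scaffolds.
#' @param gff optional GFF3 path for genome-context analyses.
#' @param rpkm,meta optional RPKM matrix / sample metadata TSVs.
#' @param catalog catalog TSV used for context analyses.
#' @param seed RNG seed recorded in the manifest.
#' @param output_dir optional directory for TSV/JSON reports.
#' @param thresholds screening thresholds ([screen_thresholds()]).
#' @param align alignment parameters ([align_params()]).
#' @param near_max,pseudocount,strong_cut,detect_floor module thresholds.
#' @return Named configuration list.
#' @export
default_config <- function(proteome = NULL, refs = NULL, gff = NULL,
                           rpkm = NULL, meta = NULL,
                           catalog = aqp_extdata("bvaqp_catalog.tsv"),
                           seed = 1L, output_dir = NULL,
                           thresholds = screen_thresholds(),
                           align = align_params(),
                           near_max = 1L, pseudocount = 1, strong_cut = 1,
                           detect_floor = 1) {
  list(proteome = proteome, refs = refs, gff = gff, rpkm = rpkm, meta = meta,
       catalog = catalog, seed = seed, output_dir = output_dir,
       thresholds = thresholds, align = align, near_max = near_max,
       pseudocount = pseudocount, strong_cut = strong_cut,
       detect_floor = detect_floor)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full annotation pipeline
#'
#' Screens the proteome, extracts residue profiles for the candidates that
#' pass, classifies them against the reference panel, calls substrates and
#' ar/R annotation notes, and (when inputs are provided) adds genome-context
#' and expression reports. Output is a pure function of (inputs, config,
#' seed); any stage failure aborts with a stage-named error and removes
#' partial outputs.
#'
#' @param config list from [default_config()].
#' @return List with `screen`, `profiles`, `annotation` (per-candidate
#'   table), `substrates`, `notes`, `context`, `expression` and `manifest`.
#' @export
run_pipeline <- function(config = default_config()) {
  for (field in c("proteome", "catalog"))
    if (is.null(config[[field]]))
      stop("config is missing required field '", field, "'")
  anchor <- stage("anchor", load_anchor())
  seqs <- stage("input", as_sequences(config$proteome))
  refs <- if (is.null(config$refs)) subgroup_scaffolds()$sequences else
    as_sequences(config$refs)
  panel <- subgroup_scaffolds()$panel

  screen <- stage("screen",
                  screen_proteome(seqs, refs, config$thresholds))
  passed <- screen$protein_id[screen$passed]

  profiles <- stage("profile", lapply(passed, function(id) {
    al <- global_align(seqs[[id]], anchor, config$align, query_id = id)
    extract_profile(al, anchor)
  }))
  names(profiles) <- passed

  classification <- stage("classify", {
    if (length(passed)) {
      dm <- build_distance_matrix(c(seqs[passed], refs), config$align)
      tree <- nj_tree(dm)
      do.call(rbind, lapply(passed, function(id)
        assign_subfamily(id, tree, panel, dm)))
    } else NULL
  })

  patterns <- load_patterns(include_novel = TRUE)
  substrates <- stage("substrate",
                      call_substrates(profiles, patterns, config$near_max))
  rules <- load_arr_rules()
  notes <- stage("substrate",
                 do.call(rbind, lapply(profiles, apply_arr_rules, rules)))

  context <- stage("context", {
    cat_df <- load_catalog(config$catalog)
    out <- list(distribution = chromosome_distribution(cat_df),
                tandem_pairs = find_tandem_pairs(cat_df))
    if (!is.null(config$gff)) {
      models <- read_gene_models(config$gff)
      out$exon_counts <- exon_counts(models)
      out$splicing <- do.call(rbind, lapply(models, detect_exon_skipping))
    }
    out
  })

  expression <- stage("expression", {
    if (!is.null(config$rpkm)) {
      em <- read_rpkm(config$rpkm, config$meta)
      responses <- list()
      leaf_ok <- "leaf" %in% colnames(em$rpkm)
      for (s in em$samples$sample_id[em$samples$condition != "control"])
        if (leaf_ok)
          responses[[s]] <- stress_response(em, s, "leaf",
                                            config$pseudocount,
                                            config$strong_cut)
      list(heatmap = heatmap_matrix(em, config$pseudocount),
           responses = responses,
           breadth = expression_breadth(em, config$detect_floor))
    } else NULL
  })

  annotation <- if (length(passed)) {
    prof_tab <- profile_table(profiles)
    full <- substrates[substrates$call == "FULL", , drop = FALSE]
    data.frame(
      protein_id = passed,
      family = classification$family,
      subgroup = classification$subgroup,
      proposed_name = classification$proposed_name,
      support = classification$support,
      method = classification$method,
      prof_tab[match(passed, prof_tab$query_id),
               setdiff(names(prof_tab), "query_id")],
      substrates_full = vapply(passed, function(id)
        paste(unique(full$substrate[full$query_id == id]), collapse = ","),
        character(1)),
      notes = vapply(passed, function(id)
        paste(notes$rule_id[notes$query_id == id], collapse = ","),
        character(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  } else NULL

  manifest <- list(
    package = "aqpkit",
    version = as.character(utils::packageVersion("aqpkit")),
    seed = config$seed,
    thresholds = config$thresholds,
    align = config$align,
    near_max = config$near_max, pseudocount = config$pseudocount,
    strong_cut = config$strong_cut, detect_floor = config$detect_floor,
    n_input = length(seqs), n_passed = length(passed))

  result <- list(screen = screen, profiles = profiles,
                 annotation = annotation, substrates = substrates,
                 notes = notes, context = context, expression = expression,
                 manifest = manifest)
  if (!is.null(config$output_dir))
    write_report(result, config$output_dir)
  result
}

# Emit the report bundle as TSV/JSON under a directory; on any failure the
# partially written files are removed.
write_report <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline stage 'report' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    emit <- function(obj, file) {
      path <- file.path(dir, file)
      write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
      written <<- c(written, path)
    }
    if (!is.null(result$annotation)) emit(result$annotation, "annotation.tsv")
    emit(result$screen, "screen.tsv")
    emit(result$substrates, "substrates.tsv")
    emit(data.frame(chromosome = names(result$context$distribution),
                    n_genes = result$context$distribution),
         "chromosome_distribution.tsv")
    emit(result$context$tandem_pairs, "tandem_pairs.tsv")
    manifest_path <- file.path(dir, "manifest.json")
    write_json(result$manifest, manifest_path, auto_unbox = TRUE,
               pretty = TRUE, digits = NA)
    written <- c(written, manifest_path)
  }, error = on_fail)
  invisible(dir)
}
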