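#' Pipeline configuration
#'
#' A pipeline run is driven by one YAML file with four blocks: top-level
#' keys (`seed`, `out_dir`, `tissue`, `n_replicates`), a `paths` block
#' (reference FASTA, GFF3, optional repeat BED, the DNA pileup and one RNA
#' pileup per replicate -- all optional when the simulation stage supplies
#' them), a `filter` block overriding [filter_config()] defaults and a
#' `simulation` block overriding [simulation_config()] defaults. The file
#' round-trips losslessly through [yaml::read_yaml()].
#'
#' @param path YAML file path; `NULL` gives the default configuration.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  }
  cfg <- list(seed = user$seed %||% 1L,
              out_dir = user$out_dir %||% "rddetect_out",
              tissue = user$tissue %||% "tissue1",
              n_replicates = user$n_replicates %||% 3L,
              paths = user$paths %||% list(),
              filter = user$filter %||% list(),
              simulation = user$simulation %||% list())
  cfg$filter_config <- do.call(filter_config, cfg$filter)
  sim_args <- cfg$simulation
  sim_args$seed <- sim_args$seed %||% cfg$seed
  if (!is.null(sim_args$edit_type_weights))
    sim_args$edit_type_weights <- unlist(sim_args$edit_type_weights)
  if (!is.null(sim_args$region_weights))
    sim_args$region_weights <- unlist(sim_args$region_weights)
  cfg$simulation_config <- do.call(simulation_config, sim_args)
  structure(cfg, class = "pipeline_config")
}

log_thresholds <- function(fc) {
  vals <- vapply(names(unclass(fc)), function(k) {
    v <- fc[[k]]
    if (is.null(v)) "auto" else paste(format(v), collapse = ",")
  }, character(1))
  message("filter thresholds in effect: ",
          paste(names(vals), vals, sep = "=", collapse = " "))
}

sim_dir <- function(config) file.path(config$out_dir, "sim")

#' Run the simulation stage
#'
#' Generates the synthetic reference, annotation, truth and pileups into
#' `<out_dir>/sim`.
#'
#' @param config a [read_pipeline_config()] result.
#' @return Invisible [simulate_rdd_dataset()] result.
#' @export
cmd_simulate <- function(config) {
  message("[simulate] seed ", config$simulation_config$seed)
  simulate_rdd_dataset(config$simulation_config, sim_dir(config),
                       n_replicates = config$n_replicates)
}

resolve_inputs <- function(config) {
  p <- config$paths
  sd <- sim_dir(config)
  pick <- function(key, default, what) {
    path <- p[[key]] %||% default
    if (is.null(path) || !file.exists(path))
      stop(sprintf("[%s] required input missing: %s (path: %s)",
                   "detect", what, path %||% "<unset>"))
    path
  }
  rna_default <- file.path(sd, sprintf("rna_rep%d.pileup.tsv",
                                       seq_len(config$n_replicates)))
  list(gff3 = pick("gff3", file.path(sd, "genes.gff3"), "gene annotation GFF3"),
       reference = pick("reference", file.path(sd, "reference.fa"),
                        "reference FASTA"),
       dna = pick("dna_pileup", file.path(sd, "dna.pileup.tsv"), "DNA pileup"),
       rna = {
         rp <- p$rna_pileups %||% rna_default
         missing <- rp[!file.exists(rp)]
         if (length(missing))
           stop("[detect] RNA pileup not found: ",
                paste(missing, collapse = ", "))
         rp
       },
       repeats = p$repeats)
}

#' Run the detection stage for every RNA replicate
#'
#' @param config a [read_pipeline_config()] result.
#' @return Invisible list of per-replicate candidate tables; side effects:
#'   `<out_dir>/detect/candidates_rep<k>.tsv` and `.vcf`.
#' @export
cmd_detect <- function(config) {
  io <- resolve_inputs(config)
  log_thresholds(config$filter_config)
  gm <- read_gff3(io$gff3)
  dna <- read_pileup_table(io$dna)
  repeats <- if (!is.null(io$repeats)) read_bed(io$repeats) else NULL
  dir <- file.path(config$out_dir, "detect")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- lapply(seq_along(io$rna), function(r) {
    rna <- read_pileup_table(io$rna[r])
    cand <- detect_rdds(dna, rna, config$filter_config, gm, repeats)
    data.table::fwrite(as.data.frame(cand),
                       file.path(dir, sprintf("candidates_rep%d.tsv", r)),
                       sep = "\t")
    write_rdd_vcf(cand, file.path(dir, sprintf("candidates_rep%d.vcf", r)))
    message(sprintf("[detect] replicate %d: %d candidates, %d PASS (%d covered positions)",
                    r, nrow(cand), sum(cand$pass), attr(cand, "n_covered")))
    cand
  })
  invisible(res)
}

#' Run the annotation stage
#'
#' Annotates each replicate's PASS candidates with type, region and coding
#' consequence.
#'
#' @param config a [read_pipeline_config()] result.
#' @param candidates optional list of candidate tables (else read back from
#'   the detect stage output).
#' @return Invisible list of annotated tables; written to
#'   `<out_dir>/annotate/annotated_rep<k>.tsv`.
#' @export
cmd_annotate <- function(config, candidates = NULL) {
  io <- resolve_inputs(config)
  gm <- read_gff3(io$gff3)
  seqs <- read_fasta(io$reference)
  if (is.null(candidates)) {
    files <- file.path(config$out_dir, "detect",
                       sprintf("candidates_rep%d.tsv",
                               seq_len(config$n_replicates)))
    if (!all(file.exists(files)))
      stop("[annotate] run cmd_detect first; missing ",
           paste(files[!file.exists(files)], collapse = ", "))
    candidates <- lapply(files, function(f)
      as.data.frame(data.table::fread(f)))
  }
  dir <- file.path(config$out_dir, "annotate")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- lapply(seq_along(candidates), function(r) {
    pass <- candidates[[r]][candidates[[r]]$pass, , drop = FALSE]
    ann <- annotate_rdds(pass, gm, seqs,
                         config$filter_config$splice_window_bp)
    data.table::fwrite(as.data.frame(ann),
                       file.path(dir, sprintf("annotated_rep%d.tsv", r)),
                       sep = "\t")
    ann
  })
  invisible(res)
}

#' Run the replicate-intersection and summary stage
#'
#' @param config a [read_pipeline_config()] result.
#' @param annotated optional list of annotated PASS tables.
#' @return Invisible list with `common` (annotated common sites) and
#'   `summary`; writes `<out_dir>/summary/` report files and a common-site
#'   VCF.
#' @export
cmd_summarize <- function(config, annotated = NULL) {
  if (is.null(annotated)) {
    files <- file.path(config$out_dir, "annotate",
                       sprintf("annotated_rep%d.tsv",
                               seq_len(config$n_replicates)))
    if (!all(file.exists(files)))
      stop("[summarize] run cmd_annotate first; missing ",
           paste(files[!file.exists(files)], collapse = ", "))
    annotated <- lapply(files, function(f)
      as.data.frame(data.table::fread(f)))
  }
  common_keys <- intersect_replicates(annotated)
  first <- annotated[[1]]
  kf <- paste(first$chrom, first$pos, first$ref, first$alt, sep = ":")
  kc <- paste(common_keys$chrom, common_keys$pos, common_keys$ref,
              common_keys$alt, sep = ":")
  common <- first[match(kc, kf), , drop = FALSE]
  common$mean_edit_ratio <- common_keys$mean_edit_ratio
  summary <- summarize_rdds(setNames(list(common), config$tissue))
  dir <- file.path(config$out_dir, "summary")
  header <- c(list(tissue = config$tissue,
                   n_replicates = length(annotated),
                   n_common = nrow(common)),
              unclass(config$filter_config))
  write_summary(summary, dir, header = header)
  data.table::fwrite(common, file.path(dir, "common_sites.tsv"), sep = "\t")
  write_rdd_vcf(common, file.path(dir, "common_sites.vcf"))
  message(sprintf("[summarize] %d common sites across %d replicates",
                  nrow(common), length(annotated)))
  invisible(list(common = common, summary = summary))
}

#' Run the whole pipeline: simulate, detect, annotate, summarize
#'
#' @param config a [read_pipeline_config()] result.
#' @return Invisible list with all stage outputs.
#' @export
cmd_run_all <- function(config) {
  sim <- cmd_simulate(config)
  cand <- cmd_detect(config)
  ann <- cmd_annotate(config, cand)
  summ <- cmd_summarize(config, ann)
  invisible(list(sim = sim, candidates = cand, annotated = ann,
                 common = summ$common, summary = summ$summary))
}
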