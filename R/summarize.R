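#' Intersect PASS candidate sets across biological replicates
#'
#' The common editing sites of a tissue are the candidates detected in
#' every replicate, matched on the full key (chrom, pos, ref, alt): the
#' same position edited to different bases in different replicates is not
#' one site. Per-replicate and mean edit ratios are reported for the
#' common set.
#'
#' @param sets non-empty list of PASS candidate data.frames (columns chrom,
#'   pos, ref, alt and optionally edit_ratio), one per replicate.
#' @return data.frame with the key columns, one `edit_ratio_<i>` column per
#'   replicate (when available) and `mean_edit_ratio`.
#' @export
intersect_replicates <- function(sets) {
  if (!length(sets)) stop("need at least one replicate set")
  keys <- lapply(sets, function(s)
    paste(s$chrom, s$pos, s$ref, s$alt, sep = ":"))
  common <- Reduce(intersect, keys)
  first <- as.data.frame(sets[[1]])
  out <- first[match(common, keys[[1]]),
               c("chrom", "pos", "ref", "alt"), drop = FALSE]
  rownames(out) <- NULL
  have_ratio <- all(vapply(sets, function(s) "edit_ratio" %in% names(s),
                           logical(1)))
  if (have_ratio && nrow(out) >= 0L) {
    for (i in seq_along(sets))
      out[[paste0("edit_ratio_", i)]] <-
        sets[[i]]$edit_ratio[match(common, keys[[i]])]
    rc <- grep("^edit_ratio_", names(out))
    out$mean_edit_ratio <- if (nrow(out))
      rowMeans(out[, rc, drop = FALSE]) else numeric(0)
  }
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Summarise common editing sites across tissues
#'
#' Produces, per tissue: the region histogram over all common sites; the
#' 12-type histogram (with fractions) over transcriptional sites (type not
#' "unassigned"); the distinct gene list excluding intergenic sites; and
#' the nonsynonymous + stop-gain site and gene counts. Across tissues, the
#' pairwise and overall gene-set overlaps are reported.
#'
#' @param tissues named list of annotated common-site data.frames
#'   ([annotate_rdds()] output restricted to the common set). A single
#'   unnamed data.frame is treated as one tissue.
#' @return list of class `rdd_summary` with one entry per tissue plus
#'   `gene_overlap` when two or more tissues are supplied.
#' @export
summarize_rdds <- function(tissues) {
  if (is.data.frame(tissues)) tissues <- list(tissue1 = tissues)
  if (is.null(names(tissues)) || any(names(tissues) == ""))
    names(tissues) <- paste0("tissue", seq_along(tissues))
  per <- lapply(tissues, function(a) {
    region <- setNames(integer(length(REGION_CLASSES)), REGION_CLASSES)
    tcount <- setNames(integer(length(RDD_TYPES)), RDD_TYPES)
    n <- nrow(a)
    if (n) {
      rt <- table(factor(a$region, levels = REGION_CLASSES))
      region[names(rt)] <- as.integer(rt)
      typed <- a$rdd_type[a$rdd_type != "unassigned"]
      tt <- table(factor(typed, levels = RDD_TYPES))
      tcount[names(tt)] <- as.integer(tt)
    }
    n_typed <- sum(tcount)
    genes <- if (n) sort(unique(unlist(
      strsplit(a$gene_ids[a$region != "intergenic" & a$gene_ids != ""], ",",
               fixed = TRUE)))) else character()
    nonsyn <- if (n) a[!is.na(a$consequence) &
                         a$consequence %in% c("nonsynonymous", "stopgain"), ,
                       drop = FALSE] else a
    nonsyn_genes <- if (nrow(nonsyn)) sort(unique(unlist(
      strsplit(nonsyn$gene_ids[nonsyn$gene_ids != ""], ",", fixed = TRUE))))
      else character()
    list(n_sites = n,
         region_counts = as.list(region),
         type_counts = as.list(tcount),
         n_typed = n_typed,
         n_unassigned = n - n_typed,
         type_fractions = as.list(if (n_typed) tcount / n_typed else tcount * 0),
         genes = genes, n_genes = length(genes),
         n_nonsyn_stopgain_sites = nrow(nonsyn),
         n_nonsyn_stopgain_genes = length(nonsyn_genes),
         nonsyn_genes = nonsyn_genes)
  })
  out <- per
  if (length(tissues) >= 2L) {
    gsets <- lapply(per, `[[`, "genes")
    pairs <- utils::combn(names(tissues), 2L, simplify = FALSE)
    overlap <- lapply(pairs, function(p)
      list(tissues = p,
           n_overlap = length(intersect(gsets[[p[1]]], gsets[[p[2]]]))))
    out$gene_overlap <- list(
      pairwise = overlap,
      n_common_all = length(Reduce(intersect, gsets)))
  }
  class(out) <- "rdd_summary"
  out
}

#' Write a summary report as JSON plus per-section TSV tables
#'
#' @param summary [summarize_rdds()] output.
#' @param dir output directory.
#' @param header optional named list recorded under `$header` (e.g. the
#'   thresholds in effect).
#' @return Invisible character vector of written paths.
#' @export
write_summary <- function(summary, dir, header = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obj <- unclass(summary)
  if (!is.null(header)) obj <- c(list(header = header), obj)
  json <- file.path(dir, "report.json")
  jsonlite::write_json(obj, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- json
  tissues <- setdiff(names(summary), "gene_overlap")
  for (ti in tissues) {
    s <- summary[[ti]]
    rg <- data.frame(region = names(s$region_counts),
                     count = unlist(s$region_counts))
    ty <- data.frame(type = names(s$type_counts),
                     count = unlist(s$type_counts),
                     fraction = unlist(s$type_fractions))
    p1 <- file.path(dir, paste0(ti, "_regions.tsv"))
    p2 <- file.path(dir, paste0(ti, "_types.tsv"))
    p3 <- file.path(dir, paste0(ti, "_genes.tsv"))
    utils::write.table(rg, p1, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ty, p2, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(s$genes, p3)
    paths <- c(paths, p1, p2, p3)
  }
  invisible(paths)
}
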