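# Plain-text readers and writers. All tables are TSV; probe coordinates are
# 0-based half-open (BED convention). Writers emit a '# nullchip' comment
# header recording the generator seed when one is attached to the object;
# readers skip '#' lines.

seed_header <- function(x) {
  s <- attr(x, "seed")
  if (is.null(s)) character(0) else paste0("# nullchip seed=", s)
}

write_tsv_with_header <- function(df, file, header = character(0)) {
  con <- file(file, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write / read a tiling design
#'
#' The probe file is a BED-like TSV (chrom, start, end, probe_id,
#' promoter_id); the gene file links promoters to genes (promoter_id,
#' gene_id, tss, strand).
#'
#' @param design a `tiling_design`.
#' @param probe_file,gene_file output (input) paths.
#' @return `write_design` returns the paths invisibly; `read_design`
#'   returns a `tiling_design` whose promoter spans are the probe extents.
#' @export
write_design <- function(design, probe_file, gene_file) {
  hdr <- seed_header(design)
  write_tsv_with_header(
    design$probes[, c("chrom", "start", "end", "probe_id", "promoter_id")],
    probe_file, hdr)
  write_tsv_with_header(design$genes, gene_file, hdr)
  invisible(c(probe_file, gene_file))
}

#' @rdname write_design
#' @export
read_design <- function(probe_file, gene_file) {
  probes <- utils::read.delim(probe_file, comment.char = "#",
                              stringsAsFactors = FALSE)
  genes <- utils::read.delim(gene_file, comment.char = "#",
                             stringsAsFactors = FALSE)
  need_p <- c("chrom", "start", "end", "probe_id", "promoter_id")
  if (!all(need_p %in% names(probes)))
    stop("probe file must have columns ", paste(need_p, collapse = ", "),
         call. = FALSE)
  need_g <- c("promoter_id", "gene_id", "tss", "strand")
  if (!all(need_g %in% names(genes)))
    stop("gene file must have columns ", paste(need_g, collapse = ", "),
         call. = FALSE)
  dup <- probes$probe_id[duplicated(probes$probe_id)]
  if (length(dup))
    stop("duplicate probe_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (any(probes$end <= probes$start))
    stop("probe intervals must have positive length", call. = FALSE)
  orphan <- is.na(probes$promoter_id) | probes$promoter_id == ""
  if (any(orphan)) {
    warning("dropping ", sum(orphan), " probe(s) outside any promoter")
    probes <- probes[!orphan, , drop = FALSE]
  }
  unknown <- !(probes$promoter_id %in% genes$promoter_id)
  if (any(unknown))
    stop("probe(s) reference unknown promoter id(s): ",
         paste(utils::head(probes$probe_id[unknown], 5), collapse = ", "),
         call. = FALSE)
  probes <- probes[order(probes$promoter_id, probes$start),
                   c("probe_id", "chrom", "start", "end", "promoter_id")]
  rownames(probes) <- NULL
  spans <- do.call(rbind, lapply(split(probes, probes$promoter_id),
    function(d) data.frame(promoter_id = d$promoter_id[1],
                           chrom = d$chrom[1],
                           region_start = min(d$start),
                           region_end = max(d$end),
                           stringsAsFactors = FALSE)))
  rownames(spans) <- NULL
  structure(list(probes = probes, promoters = spans, genes = genes),
            class = "tiling_design")
}

#' Write / read a probes-x-arrays matrix as TSV
#'
#' First column `id` holds the row names; remaining columns are arrays.
#'
#' @param mat numeric matrix with rownames.
#' @param file path.
#' @return `read_matrix_tsv` returns the matrix; the writer, the path.
#' @export
write_matrix_tsv <- function(mat, file) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_with_header(df, file, seed_header(mat))
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(file) {
  df <- utils::read.delim(file, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a per-probe score track (probe_id, value)
#'
#' @param scores named numeric vector.
#' @param file path.
#' @return `read_score_track` returns the named vector.
#' @export
write_score_track <- function(scores, file) {
  write_tsv_with_header(
    data.frame(probe_id = names(scores), value = as.numeric(scores),
               stringsAsFactors = FALSE),
    file, seed_header(scores))
}

#' @rdname write_score_track
#' @export
read_score_track <- function(file) {
  df <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(df$value, df$probe_id)
}
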