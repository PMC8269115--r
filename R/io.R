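# Bit-exact readers/writers for the plain-text formats the pipeline
# touches. TSVs are tab-separated, UTF-8, "." decimal, no quoting, fixed
# column orders. BED files are 0-based half-open; site files 1-based
# (VCF-style); every interval writer embeds a `#coords=` header line.

write_tsv_plain <- function(x, path, comment = NULL, col_names = TRUE) {
  con <- file(path, open = "wb") # binary mode: identical bytes on any OS
  on.exit(close(con))
  if (!is.null(comment)) writeLines(comment, con)
  readr::write_tsv(x, con, col_names = col_names, eol = "\n")
  invisible(path)
}

#' Read / write a wide expression table
#'
#' Genes in rows (first column `gene_id`), samples in columns.
#'
#' @param x Wide expression tibble.
#' @param path File path.
#' @return The tibble (readers) or the path, invisibly (writers).
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot("gene_id" %in% names(x))
  write_tsv_plain(x, path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read / write per-sample binned depth tables
#'
#' Columns `chrom start end depth`, 0-based half-open bins.
#'
#' @param x Depth tibble.
#' @param path File path.
#' @export
write_depth_tsv <- function(x, path) {
  write_tsv_plain(x[, c("chrom", "start", "end", "depth")], path,
                  comment = "#coords=0-based,half-open")
}

#' @rdname write_depth_tsv
#' @export
read_depth_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE,
                  col_types = readr::cols(chrom = "c", start = "d",
                                          end = "d", depth = "d"))
}

#' Read / write allele-count site tables
#'
#' Columns `chrom pos ref_t alt_t ref_n alt_n`, positions 1-based
#' (VCF convention).
#'
#' @param x Sites tibble.
#' @param path File path.
#' @export
write_sites_tsv <- function(x, path) {
  write_tsv_plain(x[, c("chrom", "pos", "ref_t", "alt_t", "ref_n", "alt_n")],
                  path, comment = "#coords=1-based")
}

#' @rdname write_sites_tsv
#' @export
read_sites_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Write segments or annotation as BED with extra columns
#'
#' 0-based half-open; the first three columns are chrom/start/end, any
#' further columns are appended after the interval.
#'
#' @param x Tibble whose first columns include chrom, start, end.
#' @param path File path.
#' @param extra_cols Character vector of additional columns to keep, in
#'   order.
#' @export
write_bed <- function(x, path, extra_cols = setdiff(names(x),
                                                    c("chrom", "start", "end"))) {
  out <- x[, c("chrom", "start", "end", extra_cols)]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  write_tsv_plain(out, path, comment = "#coords=0-based,half-open",
                  col_names = TRUE)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read / write GMT gene-set files
#'
#' Tab-separated: set name, description, then member gene ids.
#'
#' @param path File path.
#' @param sets Named list of character vectors (writer).
#' @param descriptions Optional named descriptions.
#' @return Long tibble (`set`, `gene_id`) for the reader.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  purrr::map_dfr(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop_lps("read_gmt: malformed line (need set, description, genes): ",
               substr(l, 1, 40))
    }
    tibble(set = parts[1], gene_id = parts[-(1:2)])
  })
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- purrr::imap_chr(sets, function(genes, name) {
    desc <- descriptions[[name]] %||% "na"
    paste(c(name, desc, genes), collapse = "\t")
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Emits the expression TSV, annotation BED (with `gene_id is_tf
#' hist_family` columns), per-sample tumor/normal depth TSVs, a site TSV,
#' the phenotype TSV and a manifest listing every path with the seed and a
#' config hash.
#'
#' @param cohort An `lps_cohort`.
#' @param dir Output directory (created if needed).
#' @return Manifest list, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lps_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  depth_dir <- file.path(dir, "depth")
  dir.create(depth_dir, showWarnings = FALSE)
  files <- list(
    expression = file.path(dir, "expression.tsv"),
    annotation = file.path(dir, "annotation.bed"),
    sites = file.path(dir, "sites.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    sample_info = file.path(dir, "samples.tsv")
  )
  write_expression_tsv(cohort$counts, files$expression)
  write_bed(cohort$annotation, files$annotation)
  write_tsv_plain(cohort$sites, files$sites, comment = "#coords=1-based")
  write_tsv_plain(cohort$phenotypes, files$phenotypes)
  write_tsv_plain(cohort$sample_info, files$sample_info)
  tumors <- unique(cohort$depth_tumor$sample)
  depth_files <- purrr::map(tumors, function(s) {
    ft <- file.path(depth_dir, paste0(s, ".tumor.tsv"))
    fn <- file.path(depth_dir, paste0(s, ".normal.tsv"))
    write_depth_tsv(cohort$depth_tumor[cohort$depth_tumor$sample == s, ], ft)
    write_depth_tsv(cohort$depth_normal[cohort$depth_normal$sample == s, ], fn)
    c(tumor = ft, normal = fn)
  })
  names(depth_files) <- tumors
  manifest <- list(
    seed = cohort$config$seed,
    config_hash = rlang::hash(unclass(cohort$config)),
    files = c(files, list(depth = depth_files))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
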