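# Table schemas shared by readers and writers. Each entry maps a column name
# to a readr column type.
table_schemas <- list(
  variants = list(
    sample_id = "c", variant_id = "c", vaf = "d", depth = "i",
    called = "l", supporting_reads = "i"
  ),
  baits = list(
    variant_id = "c", tumor_vaf = "d", normal_vaf = "d",
    tumor_depth = "i", normal_depth = "i", qc_flag = "c"
  ),
  read_families = list(umi = "c", site_window = "c", bases = "c"),
  site_counts = list(
    site_id = "c", mutant_reads = "i", total_reads = "i", vaf = "d",
    timepoint = "c", group = "c"
  ),
  cells = list(cell_id = "c", centroid_x = "d", centroid_y = "d")
)

read_schema_table <- function(path, schema, delim = "\t", what = path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  spec <- do.call(readr::cols, c(schema, .default = readr::col_guess()))
  out <- suppressWarnings(readr::read_delim(path,
    delim = delim, col_types = spec,
    show_col_types = FALSE, progress = FALSE
  ))
  missing <- setdiff(names(schema), names(out))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s: header does not match schema; missing column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "%s: malformed value at line %d, column %d (%s)",
      what, probs$row[1], probs$col[1], probs$expected[1]
    ))
  }
  out
}

#' Read and write the package's tabular formats
#'
#' Schema-validated TSV/CSV round-trip helpers for the tables the analysis
#' modules exchange: somatic variant tables, bait candidate tables, UMI read
#' families, site tallies, and single-cell tables. Reading validates the
#' header against the schema and reports the line and column of malformed
#' values; writing emits plain TSV (CSV for cell tables) that reads back
#' losslessly.
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return Readers return validated tibbles; writers return `x` invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_variant_table <- function(path) {
  read_schema_table(path, table_schemas$variants)
}

#' @rdname table_io
#' @export
write_variant_table <- function(x, path) {
  check_columns(x, names(table_schemas$variants), "`x`")
  readr::write_tsv(x[names(table_schemas$variants)], path)
  invisible(x)
}

#' @rdname table_io
#' @export
read_bait_table <- function(path) {
  read_schema_table(path, table_schemas$baits)
}

#' @rdname table_io
#' @export
write_bait_table <- function(x, path) {
  check_columns(x, setdiff(names(table_schemas$baits), "qc_flag"), "`x`")
  if (!"qc_flag" %in% names(x)) x$qc_flag <- NA_character_
  readr::write_tsv(x[names(table_schemas$baits)], path)
  invisible(x)
}

#' @rdname table_io
#' @export
read_read_families <- function(path) {
  read_schema_table(path, table_schemas$read_families)
}

#' @rdname table_io
#' @export
write_read_families <- function(x, path) {
  check_columns(x, names(table_schemas$read_families), "`x`")
  readr::write_tsv(x[names(table_schemas$read_families)], path)
  invisible(x)
}

#' @rdname table_io
#' @export
read_site_counts <- function(path) {
  read_schema_table(path, table_schemas$site_counts)
}

#' @rdname table_io
#' @export
write_site_counts <- function(x, path) {
  check_columns(x, c("site_id", "mutant_reads", "total_reads"), "`x`")
  for (col in c("vaf", "timepoint", "group")) {
    if (!col %in% names(x)) x[[col]] <- NA
  }
  readr::write_tsv(x[names(table_schemas$site_counts)], path)
  invisible(x)
}

#' @rdname table_io
#' @export
read_cell_table <- function(path) {
  read_schema_table(path, table_schemas$cells, delim = ",")
}

#' @rdname table_io
#' @export
write_cell_table <- function(x, path) {
  check_columns(x, names(table_schemas$cells), "`x`")
  readr::write_csv(x, path)
  invisible(x)
}

#' Read a simple-interaction-format (SIF) network
#'
#' Parses whitespace-delimited `source relation target [sign]` lines; the
#' optional fourth column carries the edge sign (+1/-1). Malformed lines are
#' reported with their line number.
#'
#' @param path Path to the SIF file.
#' @return Tibble `source`, `relation`, `target` and, when present, `sign`.
#' @export
#' @examples
#' sif <- read_sif(system.file("extdata", "demo_network.sif", package = "nof1omics"))
#' build_regulon_network(sif, unique(c(sif$source, sif$target)))
read_sif <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  parts <- strsplit(trimws(lines[keep]), "[ \t]+")
  n_fields <- lengths(parts)
  bad <- which(n_fields < 3 | n_fields > 4)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: malformed SIF line %d (expected 3 or 4 fields, found %d)",
      path, keep[bad[1]], n_fields[bad[1]]
    ))
  }
  out <- tibble(
    source = vapply(parts, `[`, character(1), 1),
    relation = vapply(parts, `[`, character(1), 2),
    target = vapply(parts, `[`, character(1), 3)
  )
  if (any(n_fields == 4)) {
    sign <- rep(NA_real_, length(parts))
    sign[n_fields == 4] <- as.numeric(vapply(
      parts[n_fields == 4], `[`, character(1), 4
    ))
    if (anyNA(sign)) {
      first <- which(is.na(sign))[1]
      abort(sprintf("%s: missing sign on SIF line %d", path, keep[first]))
    }
    out$sign <- sign
  }
  out
}

#' Write and read binary ECM masks
#'
#' Masks are stored as single-channel PNG images with a plain-text sidecar
#' (`<path>.pixel_size.txt`) carrying the pixel size in micrometres per
#' pixel.
#'
#' @param mask 0/1 or logical matrix.
#' @param path PNG file path.
#' @param pixel_size Pixel size in um/pixel.
#' @return `read_ecm_mask()` returns a list with `mask` (integer matrix) and
#'   `pixel_size`.
#' @name mask_io
NULL

#' @rdname mask_io
#' @export
write_ecm_mask <- function(mask, path, pixel_size) {
  if (pixel_size <= 0) abort("`pixel_size` must be positive")
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask)), path)
  writeLines(format(pixel_size, digits = 17), paste0(path, ".pixel_size.txt"))
  invisible(path)
}

#' @rdname mask_io
#' @export
read_ecm_mask <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  sidecar <- paste0(path, ".pixel_size.txt")
  if (!file.exists(sidecar)) {
    abort(sprintf("pixel-size sidecar not found: %s", sidecar))
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  mask <- matrix(as.integer(img > 0.5), nrow(img))
  list(mask = mask, pixel_size = as.numeric(readLines(sidecar)[1]))
}

#' Demo bait panel resembling a designed patient-specific ctDNA panel
#'
#' A deterministic 55-bait design table in which two baits (targeting INVS
#' and LILRA3) carry an inconsistent-coverage QC flag, so that panel
#' filtering yields the 53 monitored sites of a typical personalised panel.
#'
#' @return Bait tibble with `variant_id`, `gene`, VAF/depth columns and
#'   `qc_flag`.
#' @export
demo_bait_panel <- function() {
  n <- 55
  genes <- c(
    "PIK3CA", "TP53", "CCND1", "GATA3", "ESR1", "MAP3K1", "CDH1",
    "AKT1", "TYMS", "YES1", "MUC1", "STAT3", "JAK2", "RB1", "CDK4",
    "CDKN1A", "MYC", "E2F1", "MTOR", "PTEN", "BRCA1", "BRCA2", "NF1",
    "ERBB2", "KMT2C", "ARID1A", "NCOR1", "FOXA1", "TBX3", "RUNX1",
    "SF3B1", "PTPRD", "ZMYM3", "CBFB", "SPEN", "GPS2", "MED23",
    "SETD2", "ARID2", "KDM6A", "ATM", "CHEK2", "PALB2", "RAD51C",
    "FGFR1", "FGFR2", "IGF1R", "INSR", "SRC", "ABL1", "EPHA2",
    "NOTCH1", "SMAD4", "INVS", "LILRA3"
  )[seq_len(n)]
  with_seed_if(20220215, tibble(
    variant_id = sprintf("%s_snv%02d", genes, seq_len(n)),
    gene = genes,
    tumor_vaf = round(runif(n, 0.08, 0.45), 3),
    normal_vaf = round(runif(n, 0, 0.005), 4),
    tumor_depth = sample(60:180, n, replace = TRUE),
    normal_depth = sample(30:90, n, replace = TRUE),
    qc_flag = ifelse(genes %in% c("INVS", "LILRA3"),
      "inconsistent coverage", NA_character_
    )
  ))
}
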