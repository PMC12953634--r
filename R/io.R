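# Readers and writers for the minimal VCF dialect, window-count TSVs,
# intensity matrices and run configuration. All readers validate strictly
# and reject rather than coerce; every writer round-trips with its reader.

#' Write a variant table as minimal VCF v4.2
#'
#' One sample column per sample, FORMAT `GT:AD:DP` with AD as "ref,alt".
#' Genotypes are emitted as `./.` (the dialect carries depths, not calls).
#'
#' @param table a [variant_table()].
#' @param path output path (plain text).
#' @return The path, invisibly.
#' @export
write_vcf <- function(table, path) {
  check_that(inherits(table, "variant_table"), "table must be a variant_table")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tkiresist",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$samples), collapse = "\t")
  )
  gt <- matrix(sprintf("./.:%d,%d:%d", table$ad_ref, table$ad_alt, table$dp),
               nrow = nrow(table$sites))
  body <- paste(table$sites$chrom, format(table$sites$pos, scientific = FALSE,
                                          trim = TRUE),
                ".", table$sites$ref, table$sites$alt, ".", "PASS", ".",
                "GT:AD:DP",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a minimal VCF into a variant table
#'
#' Accepts the dialect written by [write_vcf()]: biallelic records whose
#' FORMAT includes AD (as "ref,alt") and DP. Multi-allelic records are
#' rejected with the offending record named; Y-chromosome records are
#' dropped (all samples treated as female/XX).
#'
#' @param path VCF path.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path) {
  check_that(file.exists(path), "no such file: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix[, c("CHROM", "POS", "REF", "ALT"), drop = FALSE],
                       stringsAsFactors = FALSE)
  check_that(nrow(fix) > 0L, "VCF %s holds no records", path)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  check_that(!any(multi),
             "multi-allelic record(s) not supported: %s",
             paste(utils::head(paste0(fix$CHROM[multi], ":", fix$POS[multi]), 3),
                   collapse = ", "))
  format_field <- v@gt[, "FORMAT"]
  has_ad <- grepl("(^|:)AD(:|$)", format_field)
  has_dp <- grepl("(^|:)DP(:|$)", format_field)
  check_that(all(has_ad) && all(has_dp),
             "FORMAT must contain AD and DP (first offending record %d)",
             which(!(has_ad & has_dp))[1])
  ad <- vcfR::extract.gt(v, "AD")
  dp <- vcfR::extract.gt(v, "DP")
  samples <- colnames(ad)
  parse_ad <- function(x, part) {
    pieces <- strsplit(x, ",", fixed = TRUE)
    bad <- lengths(pieces) != 2L
    check_that(!any(bad), "malformed AD field in record(s) %s",
               paste(utils::head(which(bad), 3), collapse = ", "))
    as.integer(vapply(pieces, `[[`, character(1), part))
  }
  ad_ref <- matrix(parse_ad(as.vector(ad), 1L), ncol = length(samples))
  ad_alt <- matrix(parse_ad(as.vector(ad), 2L), ncol = length(samples))
  dp_m <- matrix(as.integer(as.vector(dp)), ncol = length(samples))
  keep <- !is_y_chrom(fix$CHROM)
  variant_table(
    data.frame(chrom = fix$CHROM[keep], pos = as.numeric(fix$POS[keep]),
               ref = fix$REF[keep], alt = fix$ALT[keep],
               stringsAsFactors = FALSE),
    ad_ref[keep, , drop = FALSE], ad_alt[keep, , drop = FALSE],
    dp_m[keep, , drop = FALSE], samples)
}

#' Write window counts as TSV
#'
#' Four (or five, with GC) columns: chrom, start, end, count — 0-based
#' half-open coordinates, tab-separated, with a header row.
#'
#' @param windows window-count data.frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_window_counts <- function(windows, path) {
  cols <- intersect(c("chrom", "start", "end", "count", "gc"), names(windows))
  check_that(all(c("chrom", "start", "end", "count") %in% cols),
             "windows needs columns chrom, start, end, count")
  utils::write.table(windows[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a window-count TSV
#'
#' Validates the schema: numeric non-negative counts, GC (if present) in
#' [0,1], windows non-overlapping within each chromosome. Y-chromosome rows
#' are dropped (female/XX convention). Errors name the offending line
#' numbers (1-based, counting the header).
#'
#' @param path TSV path with header chrom/start/end/count[/gc].
#' @return Window-count data.frame.
#' @export
read_window_counts <- function(path) {
  check_that(file.exists(path), "no such file: %s", path)
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_that(all(c("chrom", "start", "end", "count") %in% names(w)),
             "%s: header must name chrom, start, end, count", path)
  w$chrom <- as.character(w$chrom)
  for (col in c("start", "end", "count")) {
    bad <- !is.finite(suppressWarnings(as.numeric(w[[col]])))
    check_that(!any(bad), "%s: non-numeric %s at line(s) %s", path, col,
               paste(utils::head(which(bad) + 1L, 3), collapse = ", "))
    w[[col]] <- as.numeric(w[[col]])
  }
  bad <- w$count < 0
  check_that(!any(bad), "%s: negative count at line(s) %s", path,
             paste(utils::head(which(bad) + 1L, 3), collapse = ", "))
  check_that(all(w$end > w$start), "%s: window end must exceed start", path)
  if ("gc" %in% names(w)) {
    check_that(all(w$gc >= 0 & w$gc <= 1), "%s: gc must lie in [0, 1]", path)
  }
  for (ch in unique(w$chrom)) {
    rows <- which(w$chrom == ch)
    o <- rows[order(w$start[rows])]
    ov <- which(utils::head(w$end[o], -1) > utils::tail(w$start[o], -1))
    check_that(length(ov) == 0L,
               "%s: overlapping windows at lines %d and %d", path,
               o[ov[1]] + 1L, o[ov[1] + 1L] + 1L)
  }
  w[!is_y_chrom(w$chrom), , drop = FALSE]
}

#' Read a labelled numeric matrix from CSV
#'
#' First column = feature ids (row names), remaining columns numeric.
#' Non-numeric cells are rejected with their location.
#'
#' @param path CSV path with a header row.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  check_that(file.exists(path), "no such file: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_that(ncol(d) >= 2L, "%s: need a feature column plus >= 1 sample", path)
  for (j in seq(2L, ncol(d))) {
    vals <- suppressWarnings(as.numeric(d[[j]]))
    bad <- is.na(vals) & !is.na(d[[j]]) & d[[j]] != "NA"
    check_that(!any(bad), "%s: non-numeric cell at line %d, column %s", path,
               which(bad)[1] + 1L, names(d)[j])
    d[[j]] <- vals
  }
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- as.character(d[[1L]])
  m
}

#' Write a labelled numeric matrix as CSV
#'
#' @param m numeric matrix with rownames.
#' @param path output path.
#' @param id_column header of the feature-id column (default "feature").
#' @return The path, invisibly.
#' @export
write_matrix <- function(m, path, id_column = "feature") {
  d <- data.frame(rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- id_column
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load and validate a run configuration
#'
#' YAML (or JSON) mapping of pipeline parameters; unknown keys are rejected
#' so typos cannot silently fall back to defaults. Values override the
#' defaults from [default_pipeline_config()].
#'
#' @param path YAML/JSON file path.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  check_that(file.exists(path), "no such file: %s", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(cfg), names(defaults))
  check_that(length(unknown) == 0L, "unknown config key(s): %s",
             paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, cfg)
  validate_pipeline_config(out)
  out
}
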