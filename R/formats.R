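#' Read genotype dosages from a VCF file
#'
#' Parses a VCF 4.x file into a \code{genotype_matrix}. The DS FORMAT field
#' is preferred when present; otherwise dosages are derived from GT as the
#' count of ALT alleles. Missing genotypes become NA. Multiallelic records
#' are skipped with a warning.
#'
#' @param path VCF file path (plain text or bgzip).
#' @param id_filter optional character vector of sample IDs to keep.
#' @return a \code{genotype_matrix}.
#' @export
read_vcf_dosages <- function(path, id_filter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stop("VCF contains no variant records", call. = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  fmt_keys <- unique(unlist(strsplit(v@gt[, 1], ":", fixed = TRUE)))
  if ("DS" %in% fmt_keys) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else if ("GT" %in% fmt_keys) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col) {
      vapply(col, function(g) {
        if (is.na(g)) return(NA_real_)
        al <- strsplit(g, "[/|]")[[1]]
        if (any(al == ".")) return(NA_real_)
        sum(al != "0")
      }, numeric(1), USE.NAMES = FALSE)
    })
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(fix))
  } else {
    stop("VCF records carry neither DS nor GT", call. = FALSE)
  }
  ds <- t(ds)  # individuals x variants
  if (!is.null(id_filter)) {
    missing_ids <- setdiff(id_filter, rownames(ds))
    if (length(missing_ids))
      stop("samples not in VCF: ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    ds <- ds[id_filter, , drop = FALSE]
  }
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = fix$ID, ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_matrix(ds, variants)
}

#' Write a genotype_matrix as VCF
#'
#' Emits a minimal VCF 4.2 file with GT (dosage rounded to the nearest
#' genotype) and DS FORMAT fields, one sample column per individual.
#'
#' @param genotypes a \code{genotype_matrix}.
#' @param path output path.
#' @export
write_vcf_dosages <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  dos <- genotypes$dosages
  vr <- genotypes$variants
  header <- c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dos)), collapse = "\t"))
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(vr)), function(i) {
    d <- dos[, i]
    cell <- ifelse(is.na(d), "./.:.",
                   paste0(gt_codes[pmin(pmax(round(d), 0), 2) + 1], ":",
                          formatC(d, format = "g", digits = 6)))
    paste(c(vr$chrom[i], vr$pos[i], vr$id[i], vr$ref[i], vr$alt[i],
            ".", "PASS", ".", "GT:DS", cell), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

.cohort_required <- "individual_id"
.sumstats_required <- c("CHR", "POS", "ID", "A1", "BETA", "SE", "P", "N")

#' Read / write tab-separated cohort and summary-statistic tables
#'
#' \code{read_table} reads a TSV with a header row and validates it against
#' a schema: \code{"cohort"} requires an \code{individual_id} column;
#' \code{"sumstats"} requires CHR, POS, ID, A1, BETA, SE, P, N. Cells of a
#' numeric column that fail to parse become NA, with the count recorded in
#' attribute \code{"n_unparseable"}. \code{write_table} writes numeric
#' columns with 15 significant digits so a round trip is an identity to
#' float-text precision.
#'
#' @param path TSV path.
#' @param schema one of \code{"cohort"}, \code{"sumstats"}, \code{"none"}.
#' @return data.frame with typed columns.
#' @export
read_table <- function(path, schema = c("cohort", "sumstats", "none")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  required <- switch(schema, cohort = .cohort_required,
                     sumstats = .sumstats_required, none = character(0))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  n_unparseable <- 0L
  char_cols <- c("individual_id", "ID", "CHR", "A1")
  for (j in setdiff(names(raw), char_cols)) {
    col <- raw[[j]]
    num <- suppressWarnings(as.numeric(col))
    na_like <- col %in% c("NA", "", "NaN")
    failed <- is.na(num) & !na_like
    parseable <- !is.na(num) | na_like
    if (all(parseable)) {
      raw[[j]] <- num
    } else if (mean(failed) < 0.5 && any(!is.na(num))) {
      # mostly-numeric column: unparseable cells become NA, counted
      n_unparseable <- n_unparseable + sum(failed)
      raw[[j]] <- num
    } # otherwise leave as character
  }
  attr(raw, "n_unparseable") <- n_unparseable
  raw
}

#' @rdname read_table
#' @param table data.frame to write.
#' @export
write_table <- function(table, path) {
  out <- table
  for (j in names(out)) {
    if (is.numeric(out[[j]]))
      out[[j]] <- vapply(out[[j]], function(x)
        if (is.na(x)) "NA" else formatC(x, format = "g", digits = 15),
        character(1))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a PGS-Catalog-style scoring file
#'
#' Parses a tab-separated weight file with '#' metadata lines, requiring an
#' effect-allele and an effect-weight column plus a variant key (rsID, or
#' chr_name + chr_position). Duplicate variant keys keep the first record
#' with a warning.
#'
#' @param path scoring file path.
#' @return data.frame with columns \code{variant_key},
#'   \code{effect_allele}, \code{effect_weight}.
#' @export
read_pgs_weights <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  wt_col <- intersect(c("effect_weight", "effect_weight_beta"), names(tab))
  if (!length(wt_col)) stop("schema error: no effect_weight column", call. = FALSE)
  ea_col <- intersect(c("effect_allele", "A1"), names(tab))
  if (!length(ea_col)) stop("schema error: no effect_allele column", call. = FALSE)
  if ("rsID" %in% names(tab)) {
    key <- as.character(tab$rsID)
  } else if (all(c("chr_name", "chr_position") %in% names(tab))) {
    key <- paste0(tab$chr_name, ":", tab$chr_position)
  } else {
    stop("schema error: need rsID or chr_name/chr_position columns", call. = FALSE)
  }
  if (any(!nzchar(key))) stop("empty variant key", call. = FALSE)
  w <- as.numeric(tab[[wt_col[1]]])
  if (any(!is.finite(w))) stop("non-finite effect weight", call. = FALSE)
  out <- data.frame(variant_key = key,
                    effect_allele = as.character(tab[[ea_col[1]]]),
                    effect_weight = w, stringsAsFactors = FALSE)
  dup <- duplicated(out$variant_key)
  if (any(dup)) {
    warning(sum(dup), " duplicate variant key(s); keeping first occurrence")
    out <- out[!dup, , drop = FALSE]
  }
  out
}

#' Write ground-truth or report objects as JSON
#'
#' @param x list to serialize.
#' @param path output path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
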