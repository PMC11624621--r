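#' Construct a founder population
#'
#' Bundles a variant table with a genotype matrix and (optionally) the sex of
#' each individual into the container used by all load and cross computations.
#'
#' @param variants A data frame with columns `variant_id`, `scaffold`,
#'   `position`, `impact_score` and optionally `sex_linked` (logical, default
#'   `FALSE`). Impact scores are CADD-like PHRED-scaled weights, taken as
#'   given; `(scaffold, position)` pairs must be unique and positions are
#'   1-based.
#' @param genotypes Integer matrix of deleterious-allele dosages with one row
#'   per variant (rownames = `variant_id`) and one column per individual
#'   (colnames = individual ids). Values in `{0, 1, 2, NA}`; `NA` marks a
#'   missing genotype, which is excluded from all load sums.
#' @param sex Optional named character vector mapping individual ids to
#'   `"homogametic"`, `"heterogametic"` or `"unknown"`. Individuals not named
#'   default to `"unknown"`. In birds the heterogametic sex is the female;
#'   hemizygous scoring only engages for variants flagged `sex_linked`.
#'
#' @return An object of class `load_population`: a list with elements
#'   `variants` (tibble, rows ordered as the genotype matrix), `genotypes`
#'   (integer matrix) and `sex` (named character vector).
#' @export
load_population <- function(variants, genotypes, sex = NULL) {
  variants <- validate_variants(variants)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(rownames(genotypes))) {
    if (nrow(genotypes) > 0L) stop("`genotypes` must have variant_id rownames")
    rownames(genotypes) <- character(0)
  }
  if (is.null(colnames(genotypes))) {
    stop("`genotypes` must have individual-id colnames")
  }
  if (anyDuplicated(colnames(genotypes))) {
    stop("duplicated individual ids in `genotypes`")
  }
  missing_vars <- setdiff(variants$variant_id, rownames(genotypes))
  if (length(missing_vars)) {
    stop(
      "variants without a genotype row (explicit NA required): ",
      paste(utils::head(missing_vars, 5), collapse = ", ")
    )
  }
  genotypes <- genotypes[match(variants$variant_id, rownames(genotypes)), ,
    drop = FALSE
  ]
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) {
    stop("genotype dosages must be 0, 1, 2 or NA")
  }
  ids <- colnames(genotypes)
  full_sex <- stats::setNames(rep("unknown", length(ids)), ids)
  if (!is.null(sex)) {
    bad_sex <- setdiff(sex, c("homogametic", "heterogametic", "unknown"))
    if (length(bad_sex)) {
      stop("sex must be homogametic, heterogametic or unknown")
    }
    if (is.null(names(sex)) && length(sex) == length(ids)) {
      names(sex) <- ids
    }
    unknown_ids <- setdiff(names(sex), ids)
    if (length(unknown_ids)) {
      stop("sex given for unknown individuals: ", paste(unknown_ids, collapse = ", "))
    }
    full_sex[names(sex)] <- sex
  }
  # hemizygous sites cannot carry two copies in the heterogametic sex
  if (any(variants$sex_linked)) {
    hemi <- genotypes[variants$sex_linked, full_sex[ids] == "heterogametic",
      drop = FALSE
    ]
    if (any(hemi == 2L, na.rm = TRUE)) {
      stop("invalid genotype: dosage 2 at a hemizygous (sex-linked) site in a heterogametic individual")
    }
  }
  structure(
    list(variants = variants, genotypes = genotypes, sex = full_sex),
    class = "load_population"
  )
}

validate_variants <- function(variants) {
  variants <- tibble::as_tibble(variants)
  required <- c("variant_id", "scaffold", "position", "impact_score")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"sex_linked" %in% names(variants)) {
    variants$sex_linked <- FALSE
  }
  variants$variant_id <- as.character(variants$variant_id)
  variants$scaffold <- as.character(variants$scaffold)
  variants$position <- as.integer(variants$position)
  variants$sex_linked <- as.logical(variants$sex_linked)
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicated variant_id in variant table")
  }
  if (any(is.na(variants$impact_score)) || any(variants$impact_score < 0)) {
    stop("impact_score must be nonnegative and non-missing")
  }
  if (any(!is.na(variants$position) & variants$position < 1L)) {
    stop("positions are 1-based: must be >= 1")
  }
  key <- paste(variants$scaffold, variants$position)
  if (anyDuplicated(key)) {
    stop("(scaffold, position) pairs must be unique")
  }
  variants
}

#' @export
print.load_population <- function(x, ...) {
  cat(
    "<load_population>", ncol(x$genotypes), "individuals,",
    nrow(x$variants), "variants on",
    length(unique(x$variants$scaffold)), "scaffolds\n"
  )
  invisible(x)
}

#' Individual ids of a population
#' @param pop A `load_population`.
#' @return Character vector of individual ids, in genotype-matrix column order.
#' @export
individual_ids <- function(pop) {
  stopifnot(inherits(pop, "load_population"))
  colnames(pop$genotypes)
}

#' Read a variant table from CSV/TSV
#'
#' Expects columns `variant_id`, `scaffold`, `position`, `impact_score` and
#' optionally `sex_linked`. The delimiter is sniffed from the file extension
#' (`.tsv`/`.txt` = tab, otherwise comma).
#'
#' @param path Path to the file.
#' @return A validated variant tibble.
#' @export
read_variants <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  validate_variants(utils::read.table(path,
    header = TRUE, sep = sep,
    stringsAsFactors = FALSE
  ))
}

#' Read a genotype matrix from CSV/TSV
#'
#' Rows are variants (first column `variant_id`), remaining columns are
#' individuals; cell values are deleterious-allele dosages in `{0, 1, 2, NA}`.
#'
#' @param path Path to the file.
#' @return Integer matrix with variant rownames and individual colnames.
#' @export
read_genotypes <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path,
    header = TRUE, sep = sep, stringsAsFactors = FALSE,
    check.names = FALSE
  )
  if (!"variant_id" %in% names(tab)) {
    stop("genotype file must have a variant_id column")
  }
  m <- as.matrix(tab[setdiff(names(tab), "variant_id")])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(tab$variant_id)
  m
}

#' Read genotypes (and sites) from a VCF
#'
#' Maps VCF `GT` fields to deleterious-allele dosage. Because a VCF encodes
#' REF/ALT rather than which allele is harmful, the deleterious allele must be
#' declared: either globally (`"alt"` or `"ref"`) or per site via an INFO key
#' holding the impact score of the ALT allele (sites with the key present are
#' scored on ALT dosage).
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @param deleterious `"alt"` or `"ref"`: which allele carries the load.
#' @param impact_info INFO key holding the per-site impact score (default
#'   `"CADD"`). Sites without the key are dropped with a warning.
#' @return A `load_population` (sexes `"unknown"`).
#' @export
read_vcf_population <- function(path, deleterious = c("alt", "ref"),
                                impact_info = "CADD") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_population() requires the vcfR package")
  }
  deleterious <- match.arg(deleterious)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  info <- vcfR::extract.info(v, element = impact_info, as.numeric = TRUE)
  keep <- !is.na(info)
  if (!all(keep)) {
    warning(sum(!keep), " VCF sites lack INFO/", impact_info, " and were dropped")
  }
  if (!any(keep)) stop("no VCF site carries INFO/", impact_info)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  alt_dosage <- function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
  }
  dos <- apply(gt, c(1, 2), alt_dosage)
  if (deleterious == "ref") dos <- 2L - dos
  variants <- tibble::tibble(
    variant_id = paste0(fix[, "CHROM"], "_", fix[, "POS"]),
    scaffold = as.character(fix[, "CHROM"]),
    position = as.integer(fix[, "POS"]),
    impact_score = as.numeric(info[keep])
  )
  rownames(dos) <- variants$variant_id
  load_population(variants, dos)
}
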