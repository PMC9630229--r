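#' Read genotype dosages from a VCF file
#'
#' Converts diploid GT calls (phased or unphased) to counts of the ALT
#' allele in `{0, 1, 2}` (missing calls become `NA`). The returned tibble
#' carries a `counted_allele` attribute (named by variant id, value = ALT)
#' suitable for passing to [compute_prs()], which flips orientation wherever
#' a panel's risk allele is the REF.
#'
#' @param path Path to a VCF (uncompressed or gzipped; parsed by `vcfR`).
#' @return Tibble with `participant_id` (sample names) and one dosage
#'   column per variant, named by the VCF ID field.
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Package 'vcfR' is required for VCF ingestion.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- vcfR::getID(v)
  alt <- vcfR::getALT(v)
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  })
  out <- tibble::as_tibble(t(dose))
  names(out) <- ids
  out <- dplyr::bind_cols(tibble::tibble(participant_id = colnames(gt)), out)
  attr(out, "counted_allele") <- setNames(alt, ids)
  out
}

#' Read a pipeline scenario file
#'
#' Loads a YAML or JSON scenario and merges it over [default_scenario()]:
#' top-level entries in the file override the defaults, unnamed defaults are
#' kept. Hazard specifications and subgroup specs are R objects and stay at
#' their defaults unless replaced programmatically.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param base Configuration to merge onto (default [default_scenario()]).
#' @return A configuration list for [run_pipeline()].
#' @export
read_scenario <- function(path, base = default_scenario()) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("Package 'yaml' is required for YAML scenarios.")
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      abort("Package 'jsonlite' is required for JSON scenarios.")
    }
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    abort("Scenario files must be .yaml, .yml or .json.")
  }
  merge_config(base, user)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(user[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}
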