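# File formats: count tables (VCF with per-sample allele depths, or TSV),
# JoinMap CP locus files, anchor maps, and the YAML pipeline configuration.

#' Read a count matrix from VCF or TSV
#'
#' VCF records must be biallelic SNPs with a per-sample AD field;
#' multi-allelic records are skipped (count reported via a message).  Major
#' and minor alleles are defined population-wide by total allele depth.
#' The TSV format is the long layout written by [write_counts_tsv()]:
#' columns snp_id, quality, individual, major, minor.
#'
#' @param path file path.
#' @param format "auto" (by extension), "vcf" or "tsv".
#' @return long count tibble (snp_id, quality, individual, major, minor).
#' @export
read_counts <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    out <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             snp_id = "c", quality = "d", individual = "c",
                             major = "i", minor = "i"))
    return(as_tibble(out))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  if (any(multi))
    inform(sprintf("skipping %d multi-allelic or ALT-less records",
                   sum(multi)))
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) abort("VCF has no AD field")
  keep <- which(!multi)
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  rows <- map(keep, function(i) {
    parts <- strsplit(ad[i, ], ",", fixed = TRUE)
    bad <- vapply(parts, function(x) length(x) != 2 || anyNA(suppressWarnings(
      as.integer(x))), TRUE)
    if (any(bad & !is.na(ad[i, ])))
      abort(sprintf("malformed AD at record %s", ids[[i]]))
    ref <- vapply(parts, function(x)
      if (length(x) == 2) as.integer(x[[1]]) else 0L, 1L)
    alt <- vapply(parts, function(x)
      if (length(x) == 2) as.integer(x[[2]]) else 0L, 1L)
    ref[is.na(ad[i, ])] <- 0L
    alt[is.na(ad[i, ])] <- 0L
    ref_major <- sum(ref) >= sum(alt)
    tibble(snp_id = ids[[i]], quality = qual[[i]],
           individual = colnames(ad),
           major = if (ref_major) ref else alt,
           minor = if (ref_major) alt else ref)
  })
  list_rbind(rows)
}

#' Write a count matrix as TSV
#'
#' @param counts long count tibble.
#' @param path output path.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts[c("snp_id", "quality", "individual",
                            "major", "minor")], path)
  invisible(path)
}

#' Write a count matrix as a minimal VCF with AD fields
#'
#' The major allele is written as REF (A) and the minor as ALT (B); the
#' per-SNP quality score goes to QUAL.
#'
#' @param counts long count tibble (optionally with an `lg` column used as
#'   CHROM).
#' @param path output path.
#' @export
write_counts_vcf <- function(counts, path) {
  inds <- unique(counts$individual)
  snps <- unique(counts$snp_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", inds), collapse = "\t")), con)
  wide <- counts |>
    mutate(ad = paste0(.data$major, ",", .data$minor)) |>
    select("snp_id", "quality", any_of("lg"), "individual", "ad") |>
    pivot_wider(names_from = "individual", values_from = "ad")
  for (i in seq_len(nrow(wide))) {
    chrom <- if ("lg" %in% names(wide)) wide$lg[[i]] else "1"
    writeLines(paste(c(chrom, i, wide$snp_id[[i]], "A", "B",
                       wide$quality[[i]], "PASS", ".", "AD",
                       unlist(wide[i, inds])), collapse = "\t"), con)
  }
  invisible(path)
}

# JoinMap CP phenotype coding tables per segregation class.
joinmap_code <- function(type, het_parent, calls) {
  code <- switch(type,
    ABxAA = , n1_lat = {
      hom <- setdiff(unique(na.omit(calls)), "AB")
      map_tbl <- c(AB = "lm", Bc = "lm", setNames(rep("ll", length(hom)), hom),
                   "B-" = "ll")
      list(seg = "<lmxll>", map = map_tbl)
    },
    AAxAB = , n1_moy = {
      hom <- setdiff(unique(na.omit(calls)), "AB")
      list(seg = "<nnxnp>",
           map = c(AB = "np", Bc = "np",
                   setNames(rep("nn", length(hom)), hom), "B-" = "nn"))
    },
    ABxAB = list(seg = "<hkxhk>", map = c(AA = "hh", AB = "hk", BB = "kk")),
    n3 = list(seg = "<hkxhk>", map = c(Ap = "h-", "A-" = "kk")),
    n4 = list(seg = "<abxcd>",
              map = c(AB = "ac", AA = "ad", BB = "bc", OO = "bd")),
    abort(paste0("cannot code type ", type, " for JoinMap")))
  out <- unname(code$map[calls])
  out[is.na(out)] <- "--"
  list(seg = code$seg, calls = out)
}

#' Write a JoinMap CP locus file
#'
#' Codes markers with the CP conventions (lmxll, nnxnp, hkxhk, abxcd);
#' derived null markers keep their n1/n3/n4 name prefixes.
#'
#' @param markers tibble with columns snp_id, type (ABxAA, AAxAB, ABxAB,
#'   n1, n3, n4), het_parent ("lat"/"moy", used for n1), and a `calls`
#'   list-column of named call vectors.
#' @param path output path.
#' @param pop_name population name for the header.
#' @export
write_joinmap_loc <- function(markers, path, pop_name = "cross") {
  inds <- names(markers$calls[[1]])
  lines <- c(paste0("name = ", pop_name), "popt = CP",
             paste0("nloc = ", nrow(markers)),
             paste0("nind = ", length(inds)), "")
  for (i in seq_len(nrow(markers))) {
    ty <- markers$type[[i]]
    if (is.na(ty) || ty == "rejected")
      abort(paste0("untyped marker ", markers$snp_id[[i]]))
    if (ty == "n1")
      ty <- paste0("n1_", markers$het_parent[[i]])
    jc <- joinmap_code(ty, markers$het_parent[[i]], markers$calls[[i]])
    lines <- c(lines,
               paste(markers$snp_id[[i]], jc$seg),
               paste(jc$calls, collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a JoinMap CP locus file
#'
#' Returns the loci in JoinMap coding (the inverse of
#' [write_joinmap_loc()] up to the phenotype labels, which are
#' population-specific).
#'
#' @param path file path.
#' @return tibble (snp_id, segtype, calls) with calls in JoinMap codes
#'   ("--" read back as NA).
#' @export
read_joinmap_loc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(;|$)", lines)]
  hdr <- grepl("^(name|popt|nloc|nind)\\s*=", lines)
  body <- lines[!hdr]
  stopifnot(length(body) %% 2 == 0)
  rows <- map(seq(1, length(body), by = 2), function(i) {
    head_parts <- strsplit(trimws(body[[i]]), "\\s+")[[1]]
    calls <- strsplit(trimws(body[[i + 1]]), "\\s+")[[1]]
    calls[calls == "--"] <- NA_character_
    tibble(snp_id = head_parts[[1]], segtype = head_parts[[2]],
           calls = list(calls))
  })
  list_rbind(rows)
}

#' Pipeline configuration
#'
#' All thresholds default to the published analysis values: mean depth 10
#' reads/individual, quality 10,000, heterozygosity 90%, allocation
#' R^2 > 25, classification R^2 >= 50, missingness 40 (round 1) / 45
#' (round 2), distortion p < 1e-4, OO imputation below 10% overall
#' missingness, 200 permutations at genome-wide alpha 0.05.
#'
#' @param ... overrides of the defaults.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(min_mean_depth = 10, min_quality = 10000, max_het = 90,
              alloc_r2 = 25, min_class_r2 = 50,
              max_missing_round1 = 40, missing_ge_round2 = 45,
              distortion_p = 1e-4, oo_impute_below = 0.1,
              null_alpha = 0.001, n_perm = 200, alpha = 0.05,
              map_function = "haldane", error_rate = 0.01,
              grid_step = 1, seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    abort(paste0("unknown configuration fields: ",
                 paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  stopifnot(cfg$error_rate >= 0, cfg$error_rate < 0.5, cfg$n_perm >= 20,
            cfg$alpha > 0, cfg$alpha < 1)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_config` returns a `pipeline_config`; the round trip is
#'   lossless.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
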