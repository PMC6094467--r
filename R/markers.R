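# Core representation of CP-population markers.
#
# An offspring inherits one of two homologs from each parent; the inheritance
# state at a locus is one of four classes, labelled AC, AD, BC, BD (A/B are
# the first parent's homologs -- "Latham" in the reference cross -- and C/D
# the second parent's -- "Moy").  Every marker, including derived null-allele
# markers, is fully described by its *class map*: the observed phenotype
# class emitted by each of the four states (NA = the state yields a missing
# observation, e.g. an OO genotype before imputation).  Two-point likelihoods
# and the HMM emission model are both built from class maps, so all marker
# types flow through one code path.

STATE_LABELS <- c("AC", "AD", "BC", "BD")

SEG_TYPES <- c("ABxAA", "AAxAB", "ABxAB", "ABxAO", "AOxAB", "AOxBO")

#' Phenotype class implied by a pair of inherited alleles
#'
#' Alleles are "A" (major), "B" (minor) or "O" (null, contributing no reads).
#' A genotype containing both A and B reads as heterozygous "AB"; one with
#' only A (AA or AO) reads as "AA"; only B as "BB"; OO yields no reads and is
#' missing (NA).
#'
#' @param a1,a2 character vectors of alleles in {"A","B","O"}.
#' @return character vector of classes in {"AA","AB","BB"} or NA.
#' @export
phenotype_of <- function(a1, a2) {
  has_a <- a1 == "A" | a2 == "A"
  has_b <- a1 == "B" | a2 == "B"
  out <- rep(NA_character_, length(a1))
  out[has_a & has_b] <- "AB"
  out[has_a & !has_b] <- "AA"
  out[!has_a & has_b] <- "BB"
  out
}

#' Class map of a phased marker
#'
#' @param lat1,lat2 alleles on the first parent's homologs A and B.
#' @param moy1,moy2 alleles on the second parent's homologs C and D.
#' @param oo_class if TRUE, the OO genotype is an observable class "OO"
#'   (the post-imputation coding of AOxBO markers); otherwise it is missing.
#' @return character vector of length 4 (states AC, AD, BC, BD).
#' @export
classmap_from_alleles <- function(lat1, lat2, moy1, moy2, oo_class = FALSE) {
  la <- c(lat1, lat1, lat2, lat2)
  mo <- c(moy1, moy2, moy1, moy2)
  cm <- phenotype_of(la, mo)
  if (oo_class) cm[is.na(cm) & la == "O" & mo == "O"] <- "OO"
  names(cm) <- STATE_LABELS
  cm
}

#' Flip the homolog labelling of one parent in a class map
#'
#' Swaps which homolog carries which allele -- the two phase choices at a
#' marker for that parent.
#'
#' @param cm a class map (length-4, states AC, AD, BC, BD).
#' @param parent "lat" or "moy".
#' @return the flipped class map.
#' @export
flip_classmap <- function(cm, parent = c("lat", "moy")) {
  parent <- match.arg(parent)
  idx <- if (parent == "lat") c(3L, 4L, 1L, 2L) else c(2L, 1L, 4L, 3L)
  out <- cm[idx]
  names(out) <- STATE_LABELS
  out
}

# Which parents' homolog choice affects the emitted class?  NA treated as a
# distinct symbol (a state that emits "missing" still differs from one that
# emits a class).
informative_parents <- function(cm) {
  x <- ifelse(is.na(cm), ".", cm)
  c(lat = x[1] != x[3] || x[2] != x[4],
    moy = x[1] != x[2] || x[3] != x[4])
}

# Observable classes of a marker (excluding missing).
marker_classes <- function(cm) sort(unique(cm[!is.na(cm)]))

#' Derive split and recoded null-allele markers from a phased marker
#'
#' For an ABxAO (or AOxAB) marker the B allele segregates 1:1 (the "n1"
#' marker: B carrier vs non-carrier) and the A allele shows dominant 3:1
#' segregation (the "n3" marker: A present vs absent), because AA and AO
#' phenotypes cannot be distinguished.  For an AOxBO marker the four
#' genotypes AB, AO, BO, OO are recoded as the four classes of an ABxCD
#' marker (the "n4" coding), with OO observable only after imputation.
#'
#' @param cm class map of the original marker (ignored; derivation uses the
#'   phased alleles directly).
#' @param lat1,lat2,moy1,moy2 phased parental alleles.
#' @param which one of "n1", "n3", "n4".
#' @return a class map for the derived marker.
#' @export
derive_classmap <- function(lat1, lat2, moy1, moy2,
                            which = c("n1", "n3", "n4")) {
  which <- match.arg(which)
  la <- c(lat1, lat1, lat2, lat2)
  mo <- c(moy1, moy2, moy1, moy2)
  cm <- switch(which,
    n1 = ifelse(la == "B" | mo == "B", "Bc", "B-"),
    n3 = ifelse(la == "A" | mo == "A", "Ap", "A-"),
    n4 = {
      ph <- phenotype_of(la, mo)
      ph[is.na(ph)] <- "OO"
      ph
    })
  names(cm) <- STATE_LABELS
  cm
}

# Expected offspring class frequencies under no selection: states are
# equiprobable, so tabulate the class map.
expected_class_freqs <- function(cm) {
  tab <- table(factor(cm[!is.na(cm)], levels = marker_classes(cm)))
  tab / 4
}

# Integer-coded observation matrix for a set of markers: per marker, classes
# are indexed into its own alphabet; 0 = missing.  `calls` is an m x o
# character matrix, `classmaps` a list of class maps.
encode_observations <- function(calls, classmaps) {
  m <- nrow(calls)
  out <- matrix(0L, m, ncol(calls))
  for (i in seq_len(m)) {
    cls <- marker_classes(classmaps[[i]])
    out[i, ] <- match(calls[i, ], cls, nomatch = 0L)
    out[i, is.na(calls[i, ])] <- 0L
  }
  out
}
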