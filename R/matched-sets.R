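#' Enumerate the four Mendelian transmissions of a mating
#'
#' Each parent contributes each of its two alleles once, giving the multiset
#' of the four child genotypes possible under Mendelian inheritance; the
#' observed case plus the other three members of this multiset form the 1:3
#' matched set of the genotypic TDT.
#'
#' @param father_dosage,mother_dosage non-missing parental dosages (0/1/2).
#' @return Integer vector of length 4, sorted decreasing (canonical order).
#' @export
enumerate_transmissions <- function(father_dosage, mother_dosage) {
  if (is.na(father_dosage) || is.na(mother_dosage))
    stop("set not constructible: missing parental genotype")
  stopifnot(father_dosage %in% 0:2, mother_dosage %in% 0:2)
  al <- function(g) if (g == 0L) c(0L, 0L) else if (g == 2L) c(1L, 1L) else c(0L, 1L)
  sort(as.vector(outer(al(father_dosage), al(mother_dosage), "+")),
       decreasing = TRUE)
}

#' Build one case/pseudo-control matched set
#'
#' The three pseudo-controls are the Mendelian transmission multiset minus
#' one instance of the observed case genotype; the maternal exposure vector
#' is shared by all four members (it is a property of the trio). The set is
#' skipped with a reason when it cannot be built: `MISSING_GENOTYPE` (any
#' member missing at the SNP), `MENDEL_INCONSISTENT`, or `MISSING_EXPOSURE`
#' (any requested exposure missing), checked in that order.
#'
#' @param father,mother,child dosages at one SNP.
#' @param exposures named 0/1/`NA` vector of the trio's maternal exposures.
#' @param exposure_names exposures required by the model (default none).
#' @return list with `genotypes` (length-4 integer vector: case first, then
#'   pseudo-controls in decreasing order), `exposures` (named 0/1 vector),
#'   and `informative` (FALSE iff all four genotypes are equal); or a list
#'   with element `skip` giving the reason.
#' @export
build_matched_set <- function(father, mother, child, exposures = NULL,
                              exposure_names = character(0)) {
  if (is.na(father) || is.na(mother) || is.na(child))
    return(list(skip = "MISSING_GENOTYPE"))
  if (mendel_check(father, mother, child) == "INCONSISTENT")
    return(list(skip = "MENDEL_INCONSISTENT"))
  ev <- integer(0)
  if (length(exposure_names)) {
    ev <- unlist(exposures)[exposure_names]
    if (length(ev) != length(exposure_names) || anyNA(ev))
      return(list(skip = "MISSING_EXPOSURE"))
    names(ev) <- exposure_names
  }
  trans <- enumerate_transmissions(father, mother)
  pseudo <- trans[-match(child, trans)]
  list(genotypes = c(child, sort(pseudo, decreasing = TRUE)),
       exposures = ev,
       informative = !all(trans == trans[1]))
}

# Build all matched sets for one SNP across a trio dataset.
# Returns G (n x 4 dosage matrix, case in column 1), E (n x k exposure
# matrix), family_id, informative flag, and a skip table.
build_matched_sets <- function(trios, snp, exposure_names = character(0)) {
  j <- marker_index(trios, snp)
  miss <- setdiff(exposure_names, names(trios$exposures))
  if (length(miss)) stop("exposure column absent: ", paste(miss, collapse = ", "))
  fa <- trios$geno$father[, j]; mo <- trios$geno$mother[, j]
  ch <- trios$geno$child[, j]
  Eall <- if (length(exposure_names))
    as.matrix(trios$exposures[, exposure_names, drop = FALSE])
  else matrix(0L, length(fa), 0)

  reason <- rep(NA_character_, length(fa))
  g_miss <- is.na(fa) | is.na(mo) | is.na(ch)
  reason[g_miss] <- "MISSING_GENOTYPE"
  inc <- !g_miss &
    mendel_check_vec(fa, mo, ch) == "INCONSISTENT"
  reason[inc] <- "MENDEL_INCONSISTENT"
  if (length(exposure_names)) {
    e_miss <- is.na(reason) & rowSums(is.na(Eall)) > 0
    reason[e_miss] <- "MISSING_EXPOSURE"
  }
  keep <- which(is.na(reason))

  # transmission multisets (sorted decreasing) for the 9 mating types
  trans_tab <- t(vapply(0:8, function(code)
    enumerate_transmissions(code %/% 3L, code %% 3L), integer(4)))
  G <- matrix(NA_integer_, length(keep), 4)
  if (length(keep)) {
    tr <- trans_tab[3L * fa[keep] + mo[keep] + 1L, , drop = FALSE]
    for (r in seq_along(keep)) {
      v <- tr[r, ]
      G[r, ] <- c(ch[keep[r]], v[-match(ch[keep[r]], v)])
    }
  }
  inf <- if (length(keep)) G[, 2] != G[, 4] | G[, 1] != G[, 2] else logical(0)
  fam <- trios$family_id[keep]
  rownames(G) <- fam
  E <- Eall[keep, , drop = FALSE]
  rownames(E) <- fam
  list(G = G, E = E, family_id = fam, informative = inf, snp_id = snp,
       exposure_names = exposure_names,
       skipped = data.frame(family_id = trios$family_id[!is.na(reason)],
                            reason = reason[!is.na(reason)],
                            stringsAsFactors = FALSE))
}
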