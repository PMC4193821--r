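#' Case-parent trio genotype container
#'
#' Bundles a marker panel, per-member genotype dosage matrices and a maternal
#' exposure table into a single object used by every analysis function in the
#' package. Dosages count copies of the minor allele (0, 1, 2; `NA` =
#' missing), with the minor allele defined from the parental (founder) allele
#' frequencies.
#'
#' @param markers data.frame with columns `snp_id`, `chrom`, `pos_bp`,
#'   `allele_minor`, `allele_major`; one row per marker, `snp_id` unique.
#' @param family_id character vector of unique family identifiers.
#' @param father,mother,child integer matrices (families x markers) of
#'   minor-allele dosages in \{0, 1, 2, NA\}.
#' @param exposures data.frame with a `family_id` column plus one column per
#'   binary maternal exposure coded 0/1/`NA`; may be `NULL` (no exposures).
#' @return An object of class `trio_data`.
#' @seealso [read_ped_map()], [simulate_trios()]
#' @export
trio_data <- function(markers, family_id, father, mother, child, exposures = NULL) {
  stopifnot(is.data.frame(markers))
  need <- c("snp_id", "chrom", "pos_bp", "allele_minor", "allele_major")
  if (!all(need %in% names(markers)))
    stop("markers must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(markers$snp_id))
    stop("duplicated snp_id in marker panel")
  if (any(!is.na(markers$pos_bp) & markers$pos_bp < 1))
    stop("pos_bp must be >= 1")
  same <- !is.na(markers$allele_minor) & !is.na(markers$allele_major) &
    markers$allele_minor == markers$allele_major
  if (any(same))
    stop("allele_minor equals allele_major for: ",
         paste(markers$snp_id[same], collapse = ", "))
  family_id <- as.character(family_id)
  if (anyDuplicated(family_id)) stop("duplicated family_id")
  n <- length(family_id); m <- nrow(markers)
  geno <- list(father = father, mother = mother, child = child)
  for (role in names(geno)) {
    g <- geno[[role]]
    if (!is.matrix(g) || nrow(g) != n || ncol(g) != m)
      stop(role, " genotype matrix must be ", n, " x ", m)
    if (!all(g %in% c(0L, 1L, 2L) | is.na(g)))
      stop(role, " dosages must be 0, 1, 2 or NA")
    storage.mode(g) <- "integer"
    dimnames(g) <- list(family_id, markers$snp_id)
    geno[[role]] <- g
  }
  if (is.null(exposures)) {
    exposures <- data.frame(family_id = family_id, stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(exposures), "family_id" %in% names(exposures))
    exposures$family_id <- as.character(exposures$family_id)
    # align to family order; families absent from the table get all-NA rows
    idx <- match(family_id, exposures$family_id)
    exposures <- exposures[idx, , drop = FALSE]
    exposures$family_id <- family_id
    rownames(exposures) <- NULL
    for (nm in setdiff(names(exposures), "family_id")) {
      v <- exposures[[nm]]
      if (!all(v %in% c(0L, 1L) | is.na(v)))
        stop("exposure '", nm, "' must be 0, 1 or NA")
      exposures[[nm]] <- as.integer(v)
    }
  }
  structure(list(markers = markers, family_id = family_id,
                 geno = geno, exposures = exposures),
            class = "trio_data")
}

#' @export
print.trio_data <- function(x, ...) {
  cat("Case-parent trios: ", length(x$family_id), " families, ",
      nrow(x$markers), " markers\n", sep = "")
  expo <- setdiff(names(x$exposures), "family_id")
  if (length(expo))
    cat("Maternal exposures: ", paste(expo, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.trio_data <- function(x) c(length(x$family_id), nrow(x$markers))

exposure_names <- function(x) setdiff(names(x$exposures), "family_id")

# column index of a marker, with a helpful error
marker_index <- function(trios, snp) {
  j <- match(snp, trios$markers$snp_id)
  if (is.na(j)) stop("unknown SNP: ", snp)
  j
}

#' Read trio genotypes from PLINK-style .ped/.map files
#'
#' The .ped file is whitespace-delimited with columns FID IID PAT MAT SEX
#' PHENO followed by two allele columns per marker; allele "0" means missing
#' (a half-missing genotype is treated as missing). Each family must
#' contribute exactly three rows: one child (the row whose PAT and MAT are
#' non-zero) and its two parents. The affection status column is not used:
#' all probands are assumed affected, as in an ascertained trio design.
#' Dosages are coded against the minor allele determined from the parental
#' allele frequencies (ties at 0.5 broken to the lexicographically smaller
#' allele).
#'
#' @param ped_path,map_path paths to the .ped and .map files. The .map file
#'   has 4 columns (chrom, snp_id, cM, pos_bp) or 3 (without cM).
#' @return A [trio_data] object (with an empty exposure table; see
#'   [read_exposures()]).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(map) == 4L) map <- map[, c(1, 2, 4)]
  if (ncol(map) != 3L) stop("malformed .map file: expected 3 or 4 columns")
  names(map) <- c("chrom", "snp_id", "pos_bp")
  map$pos_bp <- as.integer(map$pos_bp)
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(fields)
  if (any(len != 6L + 2L * m))
    stop("malformed .ped row length at line(s) ",
         paste(utils::head(which(len != 6L + 2L * m), 5), collapse = ", "),
         ": expected ", 6L + 2L * m, " fields")
  ped <- do.call(rbind, fields)

  fid <- ped[, 1]; iid <- ped[, 2]; pat <- ped[, 3]; mat <- ped[, 4]
  fams <- unique(fid)
  rows <- list(father = integer(0), mother = integer(0), child = integer(0))
  keep <- character(0)
  rejected <- character(0)
  for (f in fams) {
    i <- which(fid == f)
    if (anyDuplicated(iid[i]))
      stop("duplicated family member roles in family ", f)
    is_child <- pat[i] != "0" & mat[i] != "0"
    if (sum(is_child) > 1L) stop("ambiguous proband in family ", f)
    if (sum(is_child) == 0L || length(i) != 3L) {
      rejected <- c(rejected, f); next
    }
    ci <- i[is_child]
    fa <- i[iid[i] == pat[ci]]
    mo <- i[iid[i] == mat[ci]]
    if (length(fa) != 1L || length(mo) != 1L) { rejected <- c(rejected, f); next }
    keep <- c(keep, f)
    rows$father <- c(rows$father, fa)
    rows$mother <- c(rows$mother, mo)
    rows$child <- c(rows$child, ci)
  }
  if (length(rejected))
    warning("rejected ", length(rejected),
            " famil", if (length(rejected) == 1) "y" else "ies",
            " without a complete father/mother/child triple: ",
            paste(utils::head(rejected, 10), collapse = ", "))
  if (!length(keep)) stop("no complete trios in ", ped_path)

  n <- length(keep)
  dos <- list(father = matrix(NA_integer_, n, m),
              mother = matrix(NA_integer_, n, m),
              child  = matrix(NA_integer_, n, m))
  allele_minor <- allele_major <- rep(NA_character_, m)
  all_rows <- c(rows$father, rows$mother, rows$child)
  for (j in seq_len(m)) {
    a1 <- ped[, 5L + 2L * j]
    a2 <- ped[, 6L + 2L * j]
    obs <- setdiff(unique(c(a1[all_rows], a2[all_rows])), "0")
    if (length(obs) > 2L)
      stop("triallelic marker ", map$snp_id[j], ": alleles ",
           paste(sort(obs), collapse = "/"))
    if (length(obs) == 0L) next
    if (length(obs) == 1L) obs <- c(obs, if (obs == "?") "." else "?")
    ref <- sort(obs)[1]  # provisional; minor allele fixed from parents below
    miss <- a1 == "0" | a2 == "0"
    d <- (a1 == ref) + (a2 == ref)
    d[miss] <- NA_integer_
    for (role in names(rows)) dos[[role]][, j] <- d[rows[[role]]]
    mafres <- compute_maf(c(dos$father[, j], dos$mother[, j]),
                          alleles = c(sort(obs)[1], sort(obs)[2]))
    allele_minor[j] <- mafres$allele_minor
    allele_major[j] <- mafres$allele_major
    if (mafres$swapped)
      for (role in names(rows)) dos[[role]][, j] <- 2L - dos[[role]][, j]
  }
  # monomorphic/unobserved markers keep placeholder labels so the panel stays valid
  allele_major[is.na(allele_major)] <- "?"
  allele_minor[is.na(allele_minor)] <- "."
  markers <- data.frame(snp_id = map$snp_id, chrom = map$chrom,
                        pos_bp = map$pos_bp,
                        allele_minor = allele_minor, allele_major = allele_major,
                        stringsAsFactors = FALSE)
  trio_data(markers, keep, dos$father, dos$mother, dos$child)
}

#' Write trio genotypes to PLINK-style .ped/.map files
#'
#' Inverse of [read_ped_map()]: dosages are expanded to allele pairs
#' (minor/major labels from the marker panel), missing genotypes written as
#' "0 0". Parents come first in each family block; phenotype is written as 2
#' (affected) for the child and 1 for parents.
#'
#' @param trios a [trio_data] object.
#' @param ped_path,map_path output paths.
#' @return Invisibly, `trios`.
#' @export
write_ped_map <- function(trios, ped_path, map_path) {
  mk <- trios$markers
  utils::write.table(data.frame(mk$chrom, mk$snp_id, 0, mk$pos_bp),
                     map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  # d: dosage vector across markers for one individual
  pair_row <- function(d) {
    out <- rep("0 0", length(d))
    s0 <- !is.na(d) & d == 0L; s1 <- !is.na(d) & d == 1L; s2 <- !is.na(d) & d == 2L
    out[s0] <- paste(mk$allele_major[s0], mk$allele_major[s0])
    out[s1] <- paste(mk$allele_minor[s1], mk$allele_major[s1])
    out[s2] <- paste(mk$allele_minor[s2], mk$allele_minor[s2])
    out
  }
  n <- length(trios$family_id)
  con <- file(ped_path, "w"); on.exit(close(con))
  roles <- list(
    father = list(iid = "1", pat = "0", mat = "0", sex = "1", phe = "1"),
    mother = list(iid = "2", pat = "0", mat = "0", sex = "2", phe = "1"),
    child  = list(iid = "3", pat = "1", mat = "2", sex = "0", phe = "2"))
  for (i in seq_len(n)) {
    fid <- trios$family_id[i]
    for (role in names(roles)) {
      r <- roles[[role]]
      g <- pair_row(trios$geno[[role]][i, ])
      writeLines(paste(fid, paste0(fid, "_", r$iid),
                       if (role == "child") paste0(fid, "_1") else r$pat,
                       if (role == "child") paste0(fid, "_2") else r$mat,
                       r$sex, r$phe, paste(g, collapse = " ")), con)
    }
  }
  invisible(trios)
}

#' Read a maternal exposure table
#'
#' CSV with a header row; the family-ID column is `family_id` (or `FID`, or
#' the first column if neither name is present). Exposure values must be 0, 1
#' or one of the missing codes "", "NA", "-9".
#'
#' @param csv_path path to the CSV file.
#' @param exposure_names character vector of required exposure columns.
#' @return data.frame with `family_id` plus the requested exposure columns
#'   coded 0/1/`NA`.
#' @export
read_exposures <- function(csv_path, exposure_names) {
  tab <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  idcol <- intersect(c("family_id", "FID"), names(tab))
  idcol <- if (length(idcol)) idcol[1] else names(tab)[1]
  missing_cols <- setdiff(exposure_names, names(tab))
  if (length(missing_cols))
    stop("exposure column absent: ", paste(missing_cols, collapse = ", "))
  out <- data.frame(family_id = tab[[idcol]], stringsAsFactors = FALSE)
  for (nm in exposure_names) {
    v <- trimws(tab[[nm]])
    miss <- is.na(v) | v %in% c("", "NA", "-9")
    bad <- !miss & !v %in% c("0", "1")
    if (any(bad))
      stop("invalid value '", v[which(bad)[1]], "' for exposure ", nm,
           " at data row ", which(bad)[1])
    x <- suppressWarnings(as.integer(v))
    x[miss] <- NA_integer_
    out[[nm]] <- x
  }
  if (anyDuplicated(out$family_id))
    stop("duplicated family_id in exposure table")
  out
}

#' Attach a maternal exposure table to a trio dataset
#'
#' @param trios a [trio_data] object.
#' @param exposures data.frame as returned by [read_exposures()].
#' @return `trios` with the exposure columns attached; exposure-table rows for
#'   unknown families are dropped with a warning, and families without a row
#'   get `NA` exposures.
#' @export
attach_exposures <- function(trios, exposures) {
  unknown <- setdiff(exposures$family_id, trios$family_id)
  if (length(unknown))
    warning("exposure table has ", length(unknown),
            " unknown famil", if (length(unknown) == 1) "y" else "ies", ": ",
            paste(utils::head(unknown, 10), collapse = ", "))
  trio_data(trios$markers, trios$family_id, trios$geno$father,
            trios$geno$mother, trios$geno$child, exposures)
}

#' Tabulate maternal exposure rates
#'
#' Per exposure: the number exposed, the percentage exposed among trios with a
#' non-missing value (rounded to one decimal), and the number missing.
#'
#' @param trios a [trio_data] object.
#' @param exposure_names exposures to tabulate; default all attached.
#' @return data.frame with columns `exposure`, `n_trios`, `n_exposed`,
#'   `n_missing`, `pct_exposed`.
#' @export
tabulate_exposures <- function(trios, exposure_names = NULL) {
  if (is.null(exposure_names)) exposure_names <- exposure_names(trios)
  miss <- setdiff(exposure_names, names(trios$exposures))
  if (length(miss)) stop("exposure column absent: ", paste(miss, collapse = ", "))
  n <- length(trios$family_id)
  rows <- lapply(exposure_names, function(nm) {
    v <- trios$exposures[[nm]]
    n_miss <- sum(is.na(v))
    n_exp <- sum(v == 1L, na.rm = TRUE)
    denom <- n - n_miss
    data.frame(exposure = nm, n_trios = n, n_exposed = n_exp,
               n_missing = n_miss,
               pct_exposed = if (denom > 0) round(100 * n_exp / denom, 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Fixed column order of the results TSV shared by gtdt()/joint_test().
result_columns <- c("snp_id", "model", "term", "beta", "se", "wald_p",
                    "lrt_stat", "lrt_df", "lrt_p", "bonferroni_p",
                    "stratum", "or", "ci_lo", "ci_hi", "n_sets")

# skeleton ResultRow data.frame; fill what you know, defaults are NA
result_row <- function(...) {
  row <- list(snp_id = NA_character_, model = NA_character_, term = NA_character_,
              beta = NA_real_, se = NA_real_, wald_p = NA_real_,
              lrt_stat = NA_real_, lrt_df = NA_integer_, lrt_p = NA_real_,
              bonferroni_p = NA_real_, stratum = NA_character_,
              or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
              n_sets = NA_integer_)
  args <- list(...)
  row[names(args)] <- args
  as.data.frame(row[result_columns], stringsAsFactors = FALSE)
}

#' Write association results to TSV
#'
#' Fixed column order (snp_id, model, term, beta, se, wald_p, lrt_stat,
#' lrt_df, lrt_p, bonferroni_p, stratum, or, ci_lo, ci_hi, n_sets); numbers
#' are fixed-format with 6 significant digits so identical analyses produce
#' byte-identical files.
#'
#' @param results data.frame of result rows as produced by [gtdt()] or
#'   [joint_test()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path) {
  stopifnot(all(result_columns %in% names(results)))
  out <- results[, result_columns]
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      v <- formatC(out[[nm]], digits = 6, format = "g")
      v[is.na(out[[nm]])] <- "NA"
      out[[nm]] <- v
    }
  }
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
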