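#' Construct and validate a three-generation intercross pedigree
#'
#' An F2 intercross pedigree has three generations: founders (grandparents,
#' each belonging to line 1 or line 2), F1 hybrids (exactly one line-1 and
#' one line-2 founder parent — the defining property of a line-cross F1), and
#' F2 individuals (both parents F1). Generation is inferred from the parent
#' links when not supplied; deeper pedigrees are rejected.
#'
#' @param df Data frame with columns `id`, `sire`, `dam` (NA or `"."` for
#'   none), optional `sex` (`male`/`female`/`unknown`) and `line`
#'   (1/2 for founders, NA or `"."` otherwise).
#' @return A tibble of class `lo_pedigree` with columns `id`, `sire`, `dam`,
#'   `sex`, `line`, `generation`.
#' @examples
#' as_pedigree(data.frame(
#'   id = c("g1", "g2", "g3", "g4", "p1", "p2", "x1"),
#'   sire = c(NA, NA, NA, NA, "g1", "g3", "p1"),
#'   dam  = c(NA, NA, NA, NA, "g2", "g4", "p2"),
#'   sex  = c("male", "female", "male", "female", "male", "female", "unknown"),
#'   line = c(1, 2, 1, 2, NA, NA, NA)
#' ))
#' @export
as_pedigree <- function(df) {
  df <- tibble::as_tibble(df)
  if (!all(c("id", "sire", "dam") %in% names(df))) {
    stop("pedigree needs columns id, sire, dam", call. = FALSE)
  }
  none <- function(x) {
    x <- as.character(x)
    x[x %in% c(".", "", "NA")] <- NA_character_
    x
  }
  ped <- tibble::tibble(
    id = as.character(df$id),
    sire = none(df$sire),
    dam = none(df$dam),
    sex = if ("sex" %in% names(df)) as.character(df$sex) else "unknown",
    line = if ("line" %in% names(df)) {
      suppressWarnings(as.integer(none(df$line)))
    } else NA_integer_
  )
  if (anyDuplicated(ped$id)) {
    stop("duplicated pedigree ids: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_sex <- !ped$sex %in% c("male", "female", "unknown")
  if (any(bad_sex)) {
    stop("invalid sex for: ", paste(ped$id[bad_sex], collapse = ", "),
         call. = FALSE)
  }
  for (col in c("sire", "dam")) {
    ref <- ped[[col]]
    missing_parent <- !is.na(ref) & !ref %in% ped$id
    if (any(missing_parent)) {
      stop("parent records missing for: ",
           paste(unique(ref[missing_parent]), collapse = ", "), call. = FALSE)
    }
  }
  has_both <- !is.na(ped$sire) & !is.na(ped$dam)
  has_any <- !is.na(ped$sire) | !is.na(ped$dam)
  if (any(has_any & !has_both)) {
    stop("individuals with exactly one known parent: ",
         paste(ped$id[has_any & !has_both], collapse = ", "), call. = FALSE)
  }

  is_founder <- !has_both
  depth <- ifelse(is_founder, 0L, NA_integer_)
  idx <- stats::setNames(seq_len(nrow(ped)), ped$id)
  # parent links point upward only in a valid 3-generation pedigree; iterate
  # twice, anything still unresolved is a cycle or a deeper pedigree
  for (pass in 1:2) {
    unresolved <- which(is.na(depth))
    for (i in unresolved) {
      ds <- depth[idx[[ped$sire[i]]]]
      dd <- depth[idx[[ped$dam[i]]]]
      if (!is.na(ds) && !is.na(dd)) depth[i] <- max(ds, dd) + 1L
    }
  }
  if (any(is.na(depth))) {
    stop("pedigree has cycles or more than three generations; unresolved ids: ",
         paste(ped$id[is.na(depth)], collapse = ", "), call. = FALSE)
  }
  if (any(depth > 2L)) {
    stop("more than three generations; ids beyond F2: ",
         paste(ped$id[depth > 2L], collapse = ", "), call. = FALSE)
  }
  ped$generation <- c("founder", "F1", "F2")[depth + 1L]

  bad_line <- ped$generation == "founder" & !ped$line %in% c(1L, 2L)
  if (any(bad_line)) {
    stop("founders must have line 1 or 2: ",
         paste(ped$id[bad_line], collapse = ", "), call. = FALSE)
  }
  ped$line[ped$generation != "founder"] <- NA_integer_

  f1 <- which(ped$generation == "F1")
  for (i in f1) {
    lines <- sort(c(ped$line[idx[[ped$sire[i]]]], ped$line[idx[[ped$dam[i]]]]))
    if (!identical(lines, 1:2)) {
      stop("F1 individual ", ped$id[i],
           " does not have exactly one line-1 and one line-2 founder parent",
           call. = FALSE)
    }
  }
  f2 <- which(ped$generation == "F2")
  for (i in f2) {
    if (ped$sire[i] == ped$dam[i]) {
      stop("selfed F2 individual ", ped$id[i], " (sire equals dam)",
           call. = FALSE)
    }
    gen_par <- ped$generation[c(idx[[ped$sire[i]]], idx[[ped$dam[i]]])]
    if (!all(gen_par == "F1")) {
      stop("F2 individual ", ped$id[i], " has a non-F1 parent", call. = FALSE)
    }
  }
  class(ped) <- c("lo_pedigree", class(ped))
  ped
}

#' Read / write a pedigree file
#'
#' Tab-separated with header `id  sire  dam  sex  line`; `.` marks an absent
#' parent or line. Validation is as in [as_pedigree()].
#'
#' @param path File path.
#' @return For `read_pedigree()`, an `lo_pedigree` tibble.
#' @export
read_pedigree <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  as_pedigree(df)
}

#' @rdname read_pedigree
#' @param pedigree An `lo_pedigree` object.
#' @export
write_pedigree <- function(pedigree, path) {
  out <- dplyr::mutate(
    as.data.frame(pedigree)[c("id", "sire", "dam", "sex", "line")],
    sire = ifelse(is.na(.data$sire), ".", .data$sire),
    dam = ifelse(is.na(.data$dam), ".", .data$dam),
    line = ifelse(is.na(.data$line), ".", as.character(.data$line))
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Construct a genotype table
#'
#' Genotypes are unordered biallelic allele pairs; internally alleles are
#' recoded to 0/1 per marker so a genotype is one of `0/0`, `0/1`, `1/1`, or
#' missing. Rows are individuals, columns markers.
#'
#' @param df Data frame with an `id` column and one character column per map
#'   marker, entries like `"0/1"` (order-insensitive) or `NA`.
#' @param map An `lo_map`; every map marker must have a column.
#' @param pedigree An `lo_pedigree`; all genotyped individuals must occur in it.
#' @return A tibble of class `lo_geno`: column `id`, then one integer column
#'   per marker holding the dosage of allele 1 (0, 1, 2, or NA). Dosage is a
#'   complete encoding because genotypes are unordered.
#' @export
as_genotypes <- function(df, map, pedigree = NULL) {
  df <- tibble::as_tibble(df)
  if (!"id" %in% names(df)) stop("genotype table needs an `id` column", call. = FALSE)
  missing_m <- setdiff(map$marker_id, names(df))
  if (length(missing_m) > 0) {
    stop("genotype table lacks map markers: ",
         paste(utils::head(missing_m, 5), collapse = ", "),
         if (length(missing_m) > 5) ", ...", call. = FALSE)
  }
  ids <- as.character(df$id)
  if (anyDuplicated(ids)) stop("duplicated individual ids in genotype table", call. = FALSE)
  if (!is.null(pedigree)) {
    unknown <- setdiff(ids, pedigree$id)
    if (length(unknown) > 0) {
      stop("genotyped individuals absent from pedigree: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  gcols <- lapply(map$marker_id, function(m) {
    x <- df[[m]]
    if (is.numeric(x)) {
      d <- as.integer(x)
      if (any(!d %in% c(0:2, NA))) stop("bad dosage at marker ", m, call. = FALSE)
      return(d)
    }
    x <- as.character(x)
    x[x %in% c("NA", ".", "./.", "")] <- NA_character_
    parts <- strsplit(x, "/", fixed = TRUE)
    bad <- !is.na(x) & lengths(parts) != 2L
    if (any(bad)) {
      stop("malformed genotype at marker ", m, " for: ",
           paste(ids[bad], collapse = ", "), call. = FALSE)
    }
    al <- unlist(parts[!is.na(x)])
    alleles <- sort(unique(al))
    if (length(alleles) > 2) {
      stop("marker ", m, " has more than two alleles: ",
           paste(alleles, collapse = ", "), call. = FALSE)
    }
    vapply(parts, function(p) {
      if (length(p) != 2L) return(NA_integer_)
      sum(match(p, alleles) - 1L)
    }, integer(1))
  })
  names(gcols) <- map$marker_id
  out <- tibble::as_tibble(c(list(id = ids), gcols))
  class(out) <- c("lo_geno", class(out))
  out
}

#' Read / write genotype files
#'
#' Tab-separated, rows individuals, columns `id` then one per marker, entries
#' `0/0`, `0/1`, `1/1` or a missing-value sentinel (default `NA`). Alleles
#' other than 0/1 are recoded per marker; more than two alleles at a marker is
#' an error.
#'
#' @param path File path.
#' @param map,pedigree Map and pedigree the genotypes must be consistent with.
#' @param na Missing-value sentinel in the file.
#' @return For `read_genotypes()`, an `lo_geno` tibble (dosage-coded).
#' @export
read_genotypes <- function(path, map, pedigree = NULL, na = "NA") {
  df <- readr::read_tsv(path, na = c(na, ""), col_types = readr::cols(.default = readr::col_character()))
  as_genotypes(df, map, pedigree)
}

#' @rdname read_genotypes
#' @param genotypes An `lo_geno` tibble.
#' @export
write_genotypes <- function(genotypes, path, na = "NA") {
  out <- as.data.frame(genotypes)
  for (m in setdiff(names(out), "id")) {
    out[[m]] <- c("0/0", "0/1", "1/1")[out[[m]] + 1L]
  }
  out <- out[order(out$id), , drop = FALSE]
  readr::write_tsv(out, path, na = na)
  invisible(path)
}

#' Extract the dosage matrix from a genotype table
#'
#' @param genotypes An `lo_geno` tibble.
#' @return Integer matrix, individuals x markers, dosage of allele 1.
#' @keywords internal
dosage_matrix <- function(genotypes) {
  m <- as.matrix(as.data.frame(genotypes)[setdiff(names(genotypes), "id")])
  storage.mode(m) <- "integer"
  rownames(m) <- genotypes$id
  m
}

#' Write / read posterior line-origin probabilities
#'
#' Posterior files are tab-separated with columns `individual  position_cM
#' p11  p12  p21  p22  p1_maternal  p1_paternal`, where `pij` is the
#' probability that the maternal haplotype originates from line i and the
#' paternal haplotype from line j, `p1_maternal = p11 + p12` and
#' `p1_paternal = p11 + p21`. Rows are sorted by (individual, position) and
#' output is byte-deterministic given identical input.
#'
#' @param posteriors An `lo_posterior` tibble (see [infer_line_origin()]).
#' @param path File path.
#' @export
write_posteriors <- function(posteriors, path) {
  cols <- c("individual", "position_cM", "p11", "p12", "p21", "p22",
            "p1_maternal", "p1_paternal")
  out <- as.data.frame(posteriors)[cols]
  out <- out[order(out$individual, out$position_cM), , drop = FALSE]
  for (cl in cols[-1]) out[[cl]] <- sprintf("%.15g", out[[cl]])
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_posteriors
#' @export
read_posteriors <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    individual = readr::col_character(), .default = readr::col_double()
  ))
  class(out) <- c("lo_posterior", class(out))
  out
}

#' Write detected recombination switches
#'
#' Tab-separated columns: `individual  haplotype  direction  start_cM  end_cM
#' cross_cM` plus, when truth has been matched, `matched_truth` and
#' `inaccuracy_cM`. Rows sorted by (individual, haplotype, cross position).
#'
#' @param switches A switch tibble from [detect_switches()] or
#'   [match_switches()].
#' @param path File path.
#' @export
write_switches <- function(switches, path) {
  out <- as.data.frame(switches)
  out <- out[order(out$individual, out$haplotype, out$cross_cM), , drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  for (cl in names(out)[num]) {
    s <- sprintf("%.15g", out[[cl]])
    s[is.na(out[[cl]])] <- NA_character_
    out[[cl]] <- s
  }
  readr::write_tsv(out, path, na = ".")
  invisible(path)
}
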