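# Input plumbing: genotype tables, SNP maps and pedigree trios.
#
# Genotype calls are stored as the count (0/1/2) of the per-SNP "capital"
# allele -- whichever allele the input coding counts. No frequency-based
# re-orientation is performed; the models are label-symmetric.

#' Construct a genotype set
#'
#' @param calls Integer matrix (animals x SNPs) of 0/1/2 dosages with `NA`
#'   for missing; dimnames give animal and SNP identifiers.
#' @param map Data frame with columns `snp_id`, `chrom`, `pos` (1-based
#'   base-pair positions) covering every SNP.
#' @return An object of class `epitrd_genotypes`.
#' @export
genotype_set <- function(calls, map) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)), !is.null(colnames(calls)))
  if (anyDuplicated(rownames(calls))) stop("duplicated animal identifiers", call. = FALSE)
  if (anyDuplicated(colnames(calls))) stop("duplicated SNP identifiers", call. = FALSE)
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad)) {
    idx <- which(bad)[1]
    stop(sprintf(
      "invalid genotype call %s (animal %s, SNP %s); calls must be 0, 1, 2 or missing",
      calls[idx], rownames(calls)[(idx - 1) %% nrow(calls) + 1],
      colnames(calls)[(idx - 1) %/% nrow(calls) + 1]
    ), call. = FALSE)
  }
  map <- tibble::as_tibble(map)
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(map)))
  missing_map <- setdiff(colnames(calls), map$snp_id)
  if (length(missing_map)) {
    stop("map does not cover SNP(s): ", paste(head(missing_map, 5), collapse = ", "),
      call. = FALSE
    )
  }
  map <- map[match(colnames(calls), map$snp_id), c("snp_id", "chrom", "pos")]
  structure(
    list(
      calls = calls,
      animal_ids = rownames(calls), snp_ids = colnames(calls), map = map
    ),
    class = "epitrd_genotypes"
  )
}

#' @export
print.epitrd_genotypes <- function(x, ...) {
  cat(sprintf(
    "<epitrd_genotypes> %d animals x %d SNPs on %d chromosome(s); %.2f%% missing\n",
    nrow(x$calls), ncol(x$calls), dplyr::n_distinct(x$map$chrom),
    100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

.parse_call_column <- function(x, missing_codes, snp, file) {
  x[x %in% missing_codes] <- NA
  v <- suppressWarnings(as.integer(x))
  bad <- which(!is.na(x) & (is.na(v) | !(v %in% 0:2)))
  if (length(bad)) {
    stop(sprintf(
      "%s: invalid call '%s' at line %d (SNP %s); expected 0/1/2 or a missing code",
      file, x[bad[1]], bad[1] + 1L, snp
    ), call. = FALSE)
  }
  v
}

#' Read a SNP map
#'
#' Accepts PLINK `.map` files (chrom, snp_id, cM, pos; no header) or
#' tab-separated files with a header containing `snp_id`, `chrom`, `pos`.
#'
#' @param path File path.
#' @return Tibble with columns `snp_id`, `chrom` and integer `pos`.
#' @export
read_map <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("snp_id", first, fixed = TRUE)) {
    map <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else {
    map <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(map) < 4) stop(path, ": .map requires 4 columns (chrom, snp_id, cM, pos)", call. = FALSE)
    map <- data.frame(snp_id = as.character(map[[2]]), chrom = as.character(map[[1]]), pos = map[[4]])
  }
  tibble::tibble(
    snp_id = as.character(map$snp_id), chrom = as.character(map$chrom),
    pos = as.integer(map$pos)
  )
}

#' Read genotypes
#'
#' Reads biallelic SNP genotypes into 0/1/2 dosage coding. Supported
#' dialects:
#' \describe{
#'   \item{`tsv-wide`}{header `animal_id` then one column per SNP holding
#'     0/1/2 or a missing code; needs `map`.}
#'   \item{`tsv-long`}{header columns `animal_id`, `snp_id`, `call`;
#'     needs `map`.}
#'   \item{`ped`}{PLINK `.ped` with two allele symbols per SNP ("0" =
#'     missing); the companion `.map` (same stem, or `map`) gives the SNP
#'     order. The capital (counted) allele of each SNP is the
#'     alphabetically first allele observed, unless `capital_alleles`
#'     (named by SNP) says otherwise.}
#' }
#'
#' @param path Genotype file path.
#' @param format One of `"tsv-wide"`, `"tsv-long"`, `"ped"`.
#' @param map SNP map: a path accepted by [read_map()] or a data frame.
#'   For `ped`, defaults to the `.map` file next to `path`.
#' @param missing_codes Strings treated as missing calls.
#' @param capital_alleles Optional named character vector fixing the counted
#'   allele per SNP (`ped` only).
#' @return An `epitrd_genotypes` object.
#' @export
read_genotypes <- function(path, format = c("tsv-wide", "tsv-long", "ped"),
                           map = NULL, missing_codes = c("NA", "-9"),
                           capital_alleles = NULL) {
  format <- match.arg(format)
  if (format == "ped") {
    return(.read_ped(path, map, capital_alleles))
  }
  if (is.null(map)) stop("`map` is required for TSV genotype formats", call. = FALSE)
  if (is.character(map)) map <- read_map(map)
  tab <- read.table(path,
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    check.names = FALSE, colClasses = "character"
  )
  if (format == "tsv-wide") {
    if (names(tab)[1] != "animal_id") stop(path, ": first column must be 'animal_id'", call. = FALSE)
    snps <- names(tab)[-1]
    calls <- vapply(
      snps, function(s) .parse_call_column(tab[[s]], missing_codes, s, path),
      integer(nrow(tab))
    )
    calls <- matrix(calls, nrow = nrow(tab), dimnames = list(tab$animal_id, snps))
  } else {
    need <- c("animal_id", "snp_id", "call")
    if (!all(need %in% names(tab))) {
      stop(path, ": tsv-long requires columns animal_id, snp_id, call", call. = FALSE)
    }
    v <- .parse_call_column(tab$call, missing_codes, "long-format", path)
    animals <- unique(tab$animal_id)
    snps <- unique(tab$snp_id)
    calls <- matrix(NA_integer_, length(animals), length(snps),
      dimnames = list(animals, snps)
    )
    calls[cbind(match(tab$animal_id, animals), match(tab$snp_id, snps))] <- v
  }
  genotype_set(calls, map)
}

.read_ped <- function(path, map = NULL, capital_alleles = NULL) {
  if (is.null(map)) map <- sub("\\.ped$", ".map", path)
  if (is.character(map)) map <- read_map(map)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  n_snp <- nrow(map)
  width <- 6L + 2L * n_snp
  bad <- which(lengths(fields) != width)
  if (length(bad)) {
    stop(sprintf(
      "%s: malformed line %d (%d fields, expected %d for %d SNPs)",
      path, bad[1], lengths(fields)[bad[1]], width, n_snp
    ), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 2L)
  a1 <- t(vapply(fields, function(f) f[6L + 2L * seq_len(n_snp) - 1L], character(n_snp)))
  a2 <- t(vapply(fields, function(f) f[6L + 2L * seq_len(n_snp)], character(n_snp)))
  if (n_snp == 1L) {
    a1 <- matrix(a1, ncol = 1)
    a2 <- matrix(a2, ncol = 1)
  }
  calls <- matrix(NA_integer_, length(ids), n_snp, dimnames = list(ids, map$snp_id))
  for (j in seq_len(n_snp)) {
    al <- c(a1[, j], a2[, j])
    seen <- sort(setdiff(unique(al), "0"))
    if (length(seen) > 2) {
      stop(sprintf(
        "%s: SNP %s has %d allele symbols (%s); biallelic input required",
        path, map$snp_id[j], length(seen), paste(seen, collapse = ",")
      ), call. = FALSE)
    }
    cap <- if (!is.null(capital_alleles) && map$snp_id[j] %in% names(capital_alleles)) {
      capital_alleles[[map$snp_id[j]]]
    } else {
      seen[1]
    }
    miss <- a1[, j] == "0" | a2[, j] == "0"
    calls[, j] <- (a1[, j] == cap) + (a2[, j] == cap)
    calls[miss, j] <- NA_integer_
  }
  genotype_set(calls, map)
}

#' Read a pedigree of trios
#'
#' @param x File path (header `offspring_id`, `sire_id`, `dam_id`; tab or
#'   comma separated) or a data frame with those three columns (or any three
#'   columns in that order).
#' @return Tibble with columns `offspring_id`, `sire_id`, `dam_id`.
#' @export
read_trios <- function(x) {
  if (is.character(x)) {
    first <- readLines(x, n = 1)
    sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
    x <- read.table(x, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  }
  x <- as.data.frame(x)
  if (ncol(x) < 3) stop("trio table requires 3 columns (offspring, sire, dam)", call. = FALSE)
  if (!all(c("offspring_id", "sire_id", "dam_id") %in% names(x))) {
    names(x)[1:3] <- c("offspring_id", "sire_id", "dam_id")
  }
  out <- tibble::tibble(
    offspring_id = as.character(x$offspring_id),
    sire_id = as.character(x$sire_id),
    dam_id = as.character(x$dam_id)
  )
  dup <- out$offspring_id[duplicated(out$offspring_id)]
  if (length(dup)) {
    stop("offspring listed more than once: ", paste(unique(head(dup, 5)), collapse = ", "),
      call. = FALSE
    )
  }
  self <- out$offspring_id == out$sire_id | out$offspring_id == out$dam_id
  if (any(self)) {
    stop("self-parenting rows: ", paste(head(out$offspring_id[self], 5), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Write genotypes as PLINK .ped/.map
#'
#' Capital alleles are written as "1" and alternatives as "2" (so reading
#' the files back recovers the same dosages); missing calls become "0 0".
#'
#' @param genotypes An `epitrd_genotypes` object.
#' @param trios Optional trio tibble supplying sire/dam columns.
#' @param prefix Output path prefix (`prefix.ped`, `prefix.map`).
#' @return Invisibly, the two file paths.
#' @export
write_ped <- function(genotypes, prefix, trios = NULL) {
  calls <- genotypes$calls
  sire <- dam <- rep("0", nrow(calls))
  if (!is.null(trios)) {
    i <- match(rownames(calls), trios$offspring_id)
    sire[!is.na(i)] <- trios$sire_id[i[!is.na(i)]]
    dam[!is.na(i)] <- trios$dam_id[i[!is.na(i)]]
  }
  a1 <- ifelse(is.na(calls), "0", ifelse(calls >= 1, "1", "2"))
  a2 <- ifelse(is.na(calls), "0", ifelse(calls == 2, "1", "2"))
  geno_cols <- matrix("", nrow(calls), 2L * ncol(calls))
  geno_cols[, seq(1, 2 * ncol(calls), 2)] <- a1
  geno_cols[, seq(2, 2 * ncol(calls), 2)] <- a2
  ped <- cbind("FAM", rownames(calls), sire, dam, "0", "-9", geno_cols)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  write.table(ped, ped_path,
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = " "
  )
  write.table(
    data.frame(genotypes$map$chrom, genotypes$map$snp_id, 0, genotypes$map$pos),
    map_path,
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  invisible(c(ped_path, map_path))
}
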