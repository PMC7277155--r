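#' Write genotypes as PLINK text files (.ped/.map)
#'
#' Allele counts are coded with alleles A (reference) and B (counted):
#' 0 -> "A A", 1 -> "A B", 2 -> "B B", missing -> "0 0". The .map file has
#' the standard four columns (chromosome, marker id, genetic distance 0,
#' bp position); unmapped markers get chromosome 0 and position 0.
#'
#' @param geno Genotype matrix with animal rownames and marker colnames.
#' @param marker_map Tibble with `marker`, `chr`, `bp` matching the columns.
#' @param prefix File path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(geno, marker_map, prefix) {
  stopifnot(identical(colnames(geno), marker_map$marker))
  alleles <- c("A A", "A B", "B B")
  code <- function(g) ifelse(is.na(g), "0 0", alleles[g + 1L])
  ped_lines <- vapply(seq_len(nrow(geno)), function(i) {
    paste(c(rownames(geno)[i], rownames(geno)[i], 0, 0, 0, -9,
            code(geno[i, ])), collapse = " ")
  }, character(1))
  writeLines(ped_lines, paste0(prefix, ".ped"))
  map <- data.frame(
    chr = ifelse(is.na(marker_map$chr), "0", marker_map$chr),
    marker = marker_map$marker, cm = 0,
    bp = ifelse(is.na(marker_map$bp), 0L, marker_map$bp)
  )
  utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' Read PLINK text files (.ped/.map) into a genotype matrix and marker map
#'
#' Counts the B allele (or, for generic biallelic data, the
#' lexicographically later of the two alleles observed at each marker);
#' "0 0" is read as missing.
#'
#' @param prefix File path prefix of the `.ped`/`.map` pair.
#' @return A list with `geno` (integer matrix, animals x markers) and
#'   `marker_map` (tibble `marker`, `chr`, `bp`; chromosome "0" becomes
#'   `NA`).
#' @export
read_plink <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), header = FALSE,
                           colClasses = c("character", "character",
                                          "character", "integer"))
  names(map) <- c("chr", "marker", "cm", "bp")
  map$chr[map$chr == "0"] <- NA_character_
  map$bp[is.na(map$chr)] <- NA_integer_

  lines <- readLines(paste0(prefix, ".ped"))
  fields <- strsplit(trimws(lines), "[ \t]+")
  m <- nrow(map)
  geno <- matrix(NA_integer_, length(fields), m)
  ids <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 6 + 2 * m) stop_input(".ped row ", i, " has wrong length")
    ids[i] <- f[2]
    a1 <- f[seq(7, length(f), by = 2)]
    a2 <- f[seq(8, length(f), by = 2)]
    miss <- a1 == "0" | a2 == "0"
    g <- (a1 == "B") + (a2 == "B")
    g[miss] <- NA_integer_
    geno[i, ] <- g
  }
  dimnames(geno) <- list(ids, map$marker)
  list(geno = geno,
       marker_map = tibble(marker = map$marker, chr = map$chr, bp = map$bp))
}
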