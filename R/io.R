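#' Read and write pipeline flat files
#'
#' Plain-text formats: pedigree TSV (animal, sire, dam; 0 = unknown),
#' phenotype CSV (ISO-8601 dates), genotype file (one row per animal:
#' id, whitespace, contiguous dosage string over 0/1/2/5 with 5 = missing),
#' map TSV (snp, chr, pos; 1-based bp), weather CSV.
#'
#' @param ped a [Pedigree-class] or data.frame (animal, sire, dam).
#' @param file,mapFile output/input paths.
#' @return Readers return data.frames ([readGenotypes()] a
#'   [GenotypeData-class]); writers return the path invisibly.
#' @name flatfiles
NULL

#' @rdname flatfiles
#' @export
writePedigree <- function(ped, file) {
  df <- if (is(ped, "Pedigree"))
    data.frame(animal = ped@id, sire = ped@sire, dam = ped@dam) else ped
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname flatfiles
#' @export
readPedigree <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t")
  stopifnot(all(c("animal", "sire", "dam") %in% colnames(df)))
  df
}

#' Promote a pedigree table to a Pedigree object
#'
#' Sorts by animal id and validates the parent-before-offspring invariant.
#' @param df data.frame (animal, sire, dam).
#' @return A [Pedigree-class].
#' @export
pedigreeFromTable <- function(df) {
  df <- df[order(df$animal), , drop = FALSE]
  pedigree(df$animal, df$sire, df$dam)
}

#' @rdname flatfiles
#' @param phenotypes data.frame with at least animal, hcw_kg, farm, sex,
#'   litter, age_d, slaughter_date.
#' @export
writePhenotypes <- function(phenotypes, file) {
  ph <- phenotypes
  ph$slaughter_date <- format(as.Date(ph$slaughter_date))
  write.csv(ph, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname flatfiles
#' @export
readPhenotypes <- function(file) {
  ph <- read.csv(file)
  ph$slaughter_date <- as.Date(ph$slaughter_date)
  ph
}

#' @rdname flatfiles
#' @param geno a [GenotypeData-class].
#' @export
writeGenotypes <- function(geno, file, mapFile) {
  d <- geno@dosages
  d[is.na(d)] <- 5
  rows <- paste(geno@ids,
                apply(d, 1L, function(r) paste0(round(r), collapse = "")))
  writeLines(rows, file)
  map <- geno@map
  colnames(map) <- c("snp", "chr", "pos")
  write.table(map, mapFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname flatfiles
#' @export
readGenotypes <- function(file, mapFile) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed genotype row at line ", bad[1])
  ids <- vapply(parts, `[[`, "", 1L)
  strs <- vapply(parts, `[[`, "", 2L)
  badchr <- grep("[^0125]", strs)
  if (length(badchr))
    stop("invalid dosage character at line ", badchr[1],
         " (only 0, 1, 2 and 5 = missing are allowed)")
  if (length(unique(nchar(strs))) != 1L)
    stop("genotype rows have differing SNP counts")
  d <- matrix(as.numeric(unlist(strsplit(strs, ""))), nrow = length(ids),
              byrow = TRUE)
  d[d == 5] <- NA
  map <- read.table(mapFile, header = TRUE, sep = "\t")
  genotypeData(as.integer(ids), d, map)
}

#' @rdname flatfiles
#' @param weather data.frame (farm, date, tmax_c, rhmin_pct).
#' @export
writeWeather <- function(weather, file) {
  w <- weather
  w$date <- format(as.Date(w$date))
  write.csv(w, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname flatfiles
#' @export
readWeather <- function(file) {
  w <- read.csv(file)
  w$date <- as.Date(w$date)
  w
}

#' Write simulation truth as JSON
#' @param out a [SimOutput-class].
#' @param file output path.
#' @export
writeTruth <- function(out, file) {
  jsonlite::write_json(list(
    varA = out@truth$varA, covA = out@truth$covA,
    varLitter = out@truth$varLitter, varE = out@truth$varE,
    trueBV = data.frame(animal = as.integer(rownames(out@trueBV)),
                        HS = out@trueBV[, "HS"], NHS = out@trueBV[, "NHS"]),
    qtl = out@truth$qtl), file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
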