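#' Read allele protein sequences from FASTA
#'
#' Reads an IPD-IMGT/HLA- or IPD-MHC-style protein FASTA. The allele name
#' is taken from the header: the first whitespace-delimited token that
#' contains a \code{"*"} (database accessions preceding the name are
#' skipped), or the first token if none does. Sequences are uppercased on
#' read; residues outside the 20 amino acids plus \code{'X'} raise an
#' error naming the record and position.
#'
#' @param path FASTA file path.
#' @param duplicates what to do when two records share a raw allele name:
#'   \code{"error"} (default) or \code{"dedup"} (keep the first).
#' @return an \code{\linkS4class{AlleleDb}} (record order preserved).
#' @export
readAlleleFasta <- function(path, duplicates = c("error", "dedup")) {
  duplicates <- match.arg(duplicates)
  aset <- Biostrings::readAAStringSet(path)
  if (length(aset) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aset)
  nm <- vapply(headers, function(h) {
    toks <- strsplit(trimws(h), "[[:space:]]+")[[1L]]
    star <- grep("*", toks, fixed = TRUE)
    if (length(star)) toks[star[1L]] else toks[1L]
  }, character(1L), USE.NAMES = FALSE)
  seqs <- as.character(aset)
  names(seqs) <- nm
  if (anyDuplicated(nm)) {
    if (duplicates == "error")
      stop("duplicate allele names in FASTA: ",
           paste(unique(nm[duplicated(nm)]), collapse = ", "))
    seqs <- seqs[!duplicated(nm)]
  }
  alleleDb(seqs)
}

#' Write an allele database to FASTA
#'
#' One record per allele, header = raw allele name. Output is plain text
#' with fixed 60-column wrapping so identical databases serialize
#' byte-identically.
#'
#' @param db an \code{AlleleDb}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAlleleFasta <- function(db, path) {
  stopifnot(is(db, "AlleleDb"))
  con <- file(path, "w")
  on.exit(close(con))
  seqs <- as.character(db@seqs)
  for (i in seq_along(seqs)) {
    cat(">", names(seqs)[i], "\n", sep = "", file = con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    for (st in starts)
      cat(substr(s, st, min(st + 59L, nchar(s))), "\n", sep = "", file = con)
  }
  invisible(path)
}

#' Read a genotype from JSON or TSV
#'
#' JSON layout: \code{\{"id": ..., "species": ..., "loci": \{"DRB1":
#' [...], ...\}, "presenter_loci": [...]\}}. TSV layout: columns
#' \code{locus} and \code{allele} (one allele per row), with optional
#' \code{id}, \code{species} and \code{presenter} (\code{TRUE}/\code{FALSE}
#' per row's locus) columns. Allele names are parsed but not resolved
#' against any sequence database; resolution failures surface at scoring
#' time.
#'
#' @param path file path; format chosen by extension (\code{.json} vs
#'   anything else = TSV).
#' @return a \code{\linkS4class{Genotype}}.
#' @export
readGenotype <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$loci) || length(obj$loci) == 0L)
      stop("genotype file has no loci: ", path)
    loci <- lapply(obj$loci, as.character)
    g <- genotype(id = if (!is.null(obj$id)) obj$id else "genotype",
                  species = if (!is.null(obj$species)) obj$species else "unknown",
                  loci = loci,
                  presenterLoci = if (!is.null(obj$presenter_loci))
                    as.character(obj$presenter_loci) else NULL)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("empty genotype file: ", path)
    if (!all(c("locus", "allele") %in% names(df)))
      stop("genotype TSV needs 'locus' and 'allele' columns: ", path)
    loci <- split(as.character(df$allele), df$locus)
    loci <- loci[unique(df$locus)]
    presenter <- NULL
    if ("presenter" %in% names(df))
      presenter <- unique(df$locus[as.logical(df$presenter)])
    g <- genotype(id = if ("id" %in% names(df)) df$id[1L] else "genotype",
                  species = if ("species" %in% names(df)) df$species[1L]
                            else "unknown",
                  loci = loci, presenterLoci = presenter)
  }
  # validate names now so malformed files fail early
  invisible(lapply(genotypeAlleles(g), parseAlleleName))
  g
}

#' Write a genotype to JSON
#' @param g a \code{Genotype}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenotype <- function(g, path) {
  stopifnot(is(g, "Genotype"))
  obj <- list(id = g@id, species = g@species,
              loci = g@loci, presenter_loci = g@presenterLoci)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Reference SLA xenodonor genotype
#'
#' The well-characterised reference SLA genotype in common use for
#' xenotransplant studies, bundled as a plain-text genotype string
#' (caret-separated haplotype groups, plus-separated alleles) and parsed
#' with \code{\link{parseGenotypeString}}: 15 allele slots across 7 SLA
#' loci, including three SLA-1 alleles.
#'
#' @return a \code{\linkS4class{Genotype}} with id \code{"SLA-REF"}.
#' @export
slaReferenceGenotype <- function() {
  path <- system.file("extdata", "sla_reference_genotype.txt",
                      package = "xenostep", mustWork = TRUE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parseGenotypeString(txt, id = "SLA-REF", species = "swine",
                      presenterLoci = "DRB1")
}

#' Read a haplotype frequency table from TSV
#'
#' Columns: one per locus (values are allele names) plus a
#' \code{frequency} column of positive weights. Weights are normalized to
#' sum to one on load.
#'
#' @param path TSV path.
#' @param species species label for genotypes sampled from this table.
#' @return a \code{\linkS4class{HaplotypeTable}}.
#' @export
readHaplotypeTable <- function(path, species = "human") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!"frequency" %in% names(df))
    stop("haplotype TSV needs a 'frequency' column: ", path)
  w <- as.numeric(df$frequency)
  hl <- df[setdiff(names(df), "frequency")]
  haplotypeTable(hl, w, species = species)
}

#' Write a haplotype frequency table to TSV
#' @param table a \code{HaplotypeTable}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeHaplotypeTable <- function(table, path) {
  stopifnot(is(table, "HaplotypeTable"))
  df <- cbind(table@haplotypes, frequency = table@weights)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
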