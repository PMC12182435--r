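#' Run one pipeline stage and write its artifacts
#'
#' Programmatic front end tying the analysis stages together; the
#' \code{inst/scripts/xenostep-cli.R} script is a thin shell wrapper
#' around this function. Every invocation writes its declared output
#' files plus a \code{manifest.json} recording the subcommand, the fully
#' materialized configuration (all defaults filled in), the package
#' version and the output file list, so a run can be reproduced exactly
#' from its manifest. On error, partially written outputs are removed.
#'
#' Subcommands and their artifacts:
#' \describe{
#'   \item{synth}{\code{human.fasta}, \code{swine.fasta},
#'     \code{haplotypes.tsv}, \code{xenodonor.json}, \code{truth.json}.
#'     Config: the \code{\link{worldSpec}} arguments.}
#'   \item{distances}{\code{distances.tsv} from config \code{fasta}
#'     (one or more FASTA paths).}
#'   \item{tree}{\code{tree.nwk} from config \code{distances} (TSV).}
#'   \item{overlap}{\code{overlap.json} from configs \code{fastaA},
#'     \code{fastaB}, \code{k}.}
#'   \item{t2}{\code{t2.tsv}, \code{t2.json} from configs
#'     \code{recipient}, \code{donor} (genotype files), \code{fasta},
#'     \code{threshold}.}
#'   \item{step}{\code{step.tsv}, \code{step.json} from configs
#'     \code{recipient}, \code{graft1}, \code{graft2}, \code{fasta},
#'     \code{threshold}.}
#'   \item{simulate}{\code{scores.tsv}, \code{step.tsv},
#'     \code{summary.json} from configs \code{haplotypes},
#'     \code{xenodonor}, \code{fasta}, \code{nPatients}, \code{nDonors},
#'     \code{threshold}, \code{seed}.}
#' }
#'
#' @param command one of \code{"synth"}, \code{"distances"},
#'   \code{"tree"}, \code{"overlap"}, \code{"t2"}, \code{"step"},
#'   \code{"simulate"}.
#' @param config named list of subcommand settings (see Details);
#'   unspecified settings take the package defaults.
#' @param outDir output directory (created if absent).
#' @return invisibly, the list of written file paths (including the
#'   manifest).
#' @export
runPipeline <- function(command, config = list(), outDir) {
  command <- match.arg(command, c("synth", "distances", "tree", "overlap",
                                  "t2", "step", "simulate"))
  if (missing(outDir) || !nzchar(outDir)) stop("outDir is required")
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  written <- character(0)
  emit <- function(...) {
    p <- file.path(outDir, ...)
    written <<- c(written, p)
    p
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  cfg <- switch(command,
    synth = .runSynth(config, emit),
    distances = .runDistances(config, emit),
    tree = .runTree(config, emit),
    overlap = .runOverlap(config, emit),
    t2 = .runT2(config, emit),
    step = .runStep(config, emit),
    simulate = .runSimulate(config, emit))

  manifest <- list(command = command, config = cfg,
                   package = "xenostep",
                   version = as.character(utils::packageVersion("xenostep")),
                   outputs = basename(written))
  jsonlite::write_json(manifest, emit("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  ok <- TRUE
  invisible(written)
}

.cfgGet <- function(config, name, default = NULL, required = FALSE) {
  if (!is.null(config[[name]])) return(config[[name]])
  if (required) stop("missing required config entry ", sQuote(name))
  default
}

.cfgPath <- function(config, name) {
  p <- .cfgGet(config, name, required = TRUE)
  if (!file.exists(p)) stop("input file not found: ", p)
  p
}

.runSynth <- function(config, emit) {
  spec <- worldSpec(
    seed = .cfgGet(config, "seed", 1L),
    nAllelesHuman = .cfgGet(config, "nAllelesHuman", 4L),
    nAllelesSwine = .cfgGet(config, "nAllelesSwine", 3L),
    sequenceLength = .cfgGet(config, "sequenceLength", 180L),
    withinDivergence = .cfgGet(config, "withinDivergence", 5L),
    locusDivergence = .cfgGet(config, "locusDivergence", 15L),
    nSharedKmers = .cfgGet(config, "nSharedKmers", 0L),
    k = .cfgGet(config, "k", 15L),
    nHaplotypes = .cfgGet(config, "nHaplotypes", 8L))
  world <- generateWorld(spec)
  writeAlleleFasta(world$humanDb, emit("human.fasta"))
  writeAlleleFasta(world$swineDb, emit("swine.fasta"))
  writeHaplotypeTable(world$haplotypes, emit("haplotypes.tsv"))
  writeGenotype(world$xenodonor, emit("xenodonor.json"))
  jsonlite::write_json(world$truth, emit("truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(seed = spec@seed, nAllelesHuman = spec@nAllelesHuman,
       nAllelesSwine = spec@nAllelesSwine,
       sequenceLength = spec@sequenceLength,
       withinDivergence = spec@withinDivergence,
       locusDivergence = spec@locusDivergence,
       nSharedKmers = spec@nSharedKmers, k = spec@k,
       nHaplotypes = spec@nHaplotypes)
}

.readFastas <- function(paths) {
  dbs <- lapply(paths, readAlleleFasta)
  if (length(dbs) == 1L) dbs[[1L]] else do.call(c, dbs)
}

.runDistances <- function(config, emit) {
  paths <- .cfgGet(config, "fasta", required = TRUE)
  db <- .readFastas(paths)
  countGaps <- isTRUE(.cfgGet(config, "countGaps", TRUE))
  d <- distanceMatrix(db, countGaps = countGaps)
  writeDistanceTsv(d, emit("distances.tsv"))
  list(fasta = paths, countGaps = countGaps)
}

.runTree <- function(config, emit) {
  path <- .cfgPath(config, "distances")
  d <- readDistanceTsv(path)
  tree <- njTree(d)
  ape::write.tree(tree, emit("tree.nwk"))
  list(distances = path)
}

.runOverlap <- function(config, emit) {
  k <- .cfgGet(config, "k", 15L)
  denom <- .cfgGet(config, "denominator", "combined")
  a <- buildPeptidome(readAlleleFasta(.cfgPath(config, "fastaA")), k = k)
  b <- buildPeptidome(readAlleleFasta(.cfgPath(config, "fastaB")), k = k)
  ov <- overlapStats(a, b, denominator = denom)
  jsonlite::write_json(
    list(n_a = ov@nA, n_b = ov@nB, n_shared = ov@nShared,
         shared_pct = ov@sharedPct, denominator = ov@denominator),
    emit("overlap.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(fastaA = config$fastaA, fastaB = config$fastaB, k = k,
       denominator = denom)
}

.runT2 <- function(config, emit) {
  db <- .readFastas(.cfgGet(config, "fasta", required = TRUE))
  recipient <- readGenotype(.cfgPath(config, "recipient"))
  donor <- readGenotype(.cfgPath(config, "donor"))
  threshold <- .cfgGet(config, "threshold", 10)
  res <- pircheT2(recipient, donor, db, threshold = threshold)
  writeEpitopesTsv(res, emit("t2.tsv"))
  jsonlite::write_json(
    list(recipient = res@recipientId, donor = res@donorId,
         score = res@score),
    emit("t2.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(recipient = config$recipient, donor = config$donor,
       fasta = config$fasta, threshold = threshold)
}

.runStep <- function(config, emit) {
  db <- .readFastas(.cfgGet(config, "fasta", required = TRUE))
  recipient <- readGenotype(.cfgPath(config, "recipient"))
  graft1 <- readGenotype(.cfgPath(config, "graft1"))
  graft2 <- readGenotype(.cfgPath(config, "graft2"))
  threshold <- .cfgGet(config, "threshold", 10)
  res <- stepScore(recipient, graft1, graft2, db, threshold = threshold)
  writeEpitopesTsv(res, emit("step.tsv"))
  jsonlite::write_json(
    list(recipient = res@recipientId, graft1 = res@graft1Id,
         graft2 = res@graft2Id, score = res@score),
    emit("step.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(recipient = config$recipient, graft1 = config$graft1,
       graft2 = config$graft2, fasta = config$fasta,
       threshold = threshold)
}

.runSimulate <- function(config, emit) {
  db <- .readFastas(.cfgGet(config, "fasta", required = TRUE))
  table <- readHaplotypeTable(.cfgPath(config, "haplotypes"))
  xenodonor <- readGenotype(.cfgPath(config, "xenodonor"))
  nPatients <- .cfgGet(config, "nPatients", 100L)
  nDonors <- .cfgGet(config, "nDonors", 50L)
  threshold <- .cfgGet(config, "threshold", 10)
  seed <- .cfgGet(config, "seed", 1L)
  summary <- simulateCohort(table, xenodonor, db, nPatients, nDonors,
                            threshold = threshold, seed = seed)
  tmem <- repeatTransplantAnalysis(table, xenodonor, db, nPatients,
                                   nDonors, threshold = threshold,
                                   seed = seed)
  utils::write.table(summary@scores, emit("scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tmem$steps, emit("step.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_patients = summary@nPatients, n_donors = summary@nDonors,
         seed = summary@seed, threshold = summary@threshold,
         best_patients = summary@bestPatients,
         worst_patients = summary@worstPatients,
         patient_medians = summary@patientMedians,
         tmem_summary = tmem$summary),
    emit("summary.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(haplotypes = config$haplotypes, xenodonor = config$xenodonor,
       fasta = config$fasta, nPatients = nPatients, nDonors = nDonors,
       threshold = threshold, seed = seed)
}
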