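#' Read DNA sequences from a FASTA file
#'
#' Sequences are returned as a named character vector in the {A,C,G,T,N}
#' alphabet.  Lowercase letters are uppercased and `U` is mapped to `T`
#' (a note is emitted when this happens); any other IUPAC ambiguity code is
#' replaced by `N`.  Record ids must be unique within one file.
#'
#' @param path FASTA file (multi-record allowed).
#' @return Named character vector of sequences; full header lines are kept
#'   in the `"description"` attribute.
#' @export
read_dna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(grepl("U", seqs, fixed = TRUE))) {
    message("note: U residues mapped to T on load")
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
  }
  seqs <- gsub("[^ACGTN]", "N", seqs)
  if (any(!nzchar(seqs))) stop("empty sequence record in ", path)
  names(seqs) <- ids
  attr(seqs, "description") <- headers
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_dna_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' @param seq Character scalar over {A,C,G,T,N} (U tolerated, treated as T).
#' @return Reverse-complemented character scalar.
#' @export
revcomp <- function(seq) {
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## one sequence -> integer codes 1..4 (A,C,G,T), NA for anything else
.seq_codes <- function(seq) {
  m <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]],
             c("A", "C", "G", "T"))
  m
}

.gc_fraction <- function(seq) {
  codes <- .seq_codes(seq)
  codes <- codes[!is.na(codes)]
  if (!length(codes)) return(NA_real_)
  mean(codes == 2L | codes == 3L)
}

#' Default run configuration
#'
#' All tunable parameters of the pipeline with their default values, as a
#' nested list keyed by module.  The defaults match the settings used
#' throughout the package: 40-bp dinucleotide-usage windows, 147-bp
#' nucleosomal frame with a 10.3-bp helical repeat, 30-bp curvature window,
#' SymCurv flank half-width m = 25, 80% PWM relative-score threshold,
#' homology scan at 68% identity with the GGCTCCTGCC consensus and a
#' -36 kcal/mol duplex cutoff, and isochore segmentation at t0 = 100 with a
#' 3000-bp minimum segment.
#'
#' @return Nested list of parameters.
#' @export
default_config <- function() {
  list(
    core_io = list(
      levenshtein_window = 100L, levenshtein_step = 20L,
      isochore_t0 = 100, isochore_min_length = 3000L,
      isochore_cutoffs = c(L1 = 0.37, L2 = 0.41, H1 = 0.46, H2 = 0.52),
      mask_n_fraction = 0.10
    ),
    nps_profile = list(
      window = 40L, step = 1L, expected_dinuc_freq = 0.0625,
      helical_repeat = 10.3, frame = 147L
    ),
    symcurv = list(
      curvature_window = 30L, twist = 34.3, m = 25L, epsilon = 1e-6,
      smin_mode = "second_difference"
    ),
    oscillation_align = list(
      max_shift = 10L, n_boot = 1000L, segment = 20L, min_overlap = 0.5
    ),
    cis_motif = list(
      rel_threshold = 0.80, pseudocount = 0.8,
      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
    ),
    mirhr_scan = list(
      min_identity = 0.68, consensus = "GGCTCCTGCC", dg_max = -36,
      mismatch_penalty = 3.0, initiation = 4.09
    ),
    noise_stats = list(
      timepoints = paste0("t", seq(0L, 180L, by = 20L)),
      reference_timepoint = "t0", statistic = "max"
    ),
    synthetic_data = list(
      gc = 0.5, n_genes = 43L,
      burst_frequency = 0.15, burst_size_mean = 20, decay_rate = 0.15,
      basal_rate = 0.1, n_cells = 100L, suppression_window = c(80, 100),
      suppression_factor = 0.35, amplification_factor = 1.0
    )
  )
}

#' Read a run configuration from a YAML file
#'
#' Values present in the file override the defaults; keys that do not exist
#' in [default_config()] are rejected so that typos fail loudly.
#'
#' @param path YAML config file.
#' @return Nested parameter list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (is.null(user)) return(cfg)
  for (mod in names(user)) {
    if (!mod %in% names(cfg)) stop("unknown config section: ", mod)
    for (key in names(user[[mod]])) {
      if (!key %in% names(cfg[[mod]])) {
        stop("unknown config key: ", mod, ".", key)
      }
      val <- user[[mod]][[key]]
      # YAML maps come back as named lists; defaults use atomic vectors
      default <- cfg[[mod]][[key]]
      if (is.atomic(default) && is.list(val)) val <- unlist(val)
      if (!is.null(names(default)) && is.null(names(val)) &&
          length(val) == length(default)) {
        names(val) <- names(default)
      }
      cfg[[mod]][[key]] <- val
    }
  }
  cfg
}

#' Write a run configuration to YAML
#' @param cfg Nested parameter list.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
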