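#' qPCR assay panel used for validation
#'
#' The nine TaqMan assays used in the validation arm of the study design this
#' package models: four platelet-derived miRNAs, three RBC-derived miRNAs
#' (miR-451a doubling as the hemolysis indicator together with miR-23a-3p),
#' and the normalization control miR-30e-5p. Mature sequences are stored in
#' the DNA alphabet (U -> T).
#'
#' @return A data.frame with columns \code{name}, \code{sequence},
#'   \code{role}.
#' @export
qpcr_assay_panel <- function() {
  data.frame(
    name = c("miR-223-3p", "miR-126-3p", "miR-21-5p", "miR-150-5p",
             "miR-16-5p", "miR-92a-3p", "miR-451a", "miR-23a-3p",
             "miR-30e-5p"),
    sequence = c("TGTCAGTTTGTCAAATACCCCA",
                 "TCGTACCGTGAGTAATAATGCG",
                 "TAGCTTATCAGACTGATGTTGA",
                 "TCTCCCAACCCTTGTACCAGTG",
                 "TAGCAGCACGTAAATATTGGCG",
                 "TATTGCACTTGTCCCGGCCTGT",
                 "AAACCGTTACCATTACTGAGTT",
                 "ATCACATTGCCAGGGATTTCC",
                 "TGTAAACATCCTTGACTGGAAG"),
    role = c("platelet", "platelet", "platelet", "platelet",
             "rbc", "rbc", "rbc/hemolysis", "hemolysis",
             "normalization"),
    stringsAsFactors = FALSE
  )
}

# Named miRNAs guaranteed to be present in every generated reference, in
# priority order: the ten sentinel names used by the scoring panels first
# (with real mature sequences where the assay panel provides them), then the
# remaining default origin-panel members with synthetic sequences.
sentinel_mirnas <- function() {
  c("miR-451a", "miR-23a-3p", "miR-486-5p", "miR-92a-3p", "miR-16-5p",
    "miR-223-3p", "miR-126-3p", "miR-21-5p", "miR-150-5p", "miR-30e-5p",
    "miR-191-5p", "miR-25-3p", "miR-484", "miR-93-5p", "miR-181a-5p",
    "miR-486-3p", "miR-103a-3p", "miR-320a", "miR-27b-3p", "miR-199a-3p",
    "miR-185-5p", "miR-144-3p", "miR-144-5p", "miR-4732-3p", "miR-425-5p",
    "miR-15b-5p", "miR-16-2-3p")
}

#' Generate a synthetic hairpin-anchored mature miRNA reference
#'
#' Builds a miRBase-style reference for simulation and testing: each mature
#' miRNA (18-25 nt) is embedded in a longer hairpin precursor at recorded
#' 0-based half-open coordinates, so that templated/non-templated end
#' modifications of reads can be called against real flanking context.
#' The reference always contains the sentinel miRNAs used by the hemolysis
#' and origin panels (see \code{\link{qpcr_assay_panel}}); sentinels covered
#' by the assay panel carry their real mature sequences, all other mature
#' sequences are synthetic.
#'
#' @param n_mirnas number of mature miRNAs (>= 1).
#' @param seed integer seed; the same seed always yields the same reference.
#' @param flank hairpin flank length on each side of the mature sequence.
#' @return An object of class \code{mirna_reference}: a list with data.frames
#'   \code{mature} (name, sequence, hairpin_id, start, end) and
#'   \code{hairpin} (id, sequence).
#' @export
generate_reference <- function(n_mirnas = 350L, seed = 1L, flank = 20L) {
  stopifnot(n_mirnas >= 1L, flank >= 4L)
  with_seed(derive_seed(seed, "reference"), {
    sent <- sentinel_mirnas()
    assay <- qpcr_assay_panel()
    n_named <- min(n_mirnas, length(sent))
    names_named <- sent[seq_len(n_named)]
    n_syn <- n_mirnas - n_named
    names_syn <- if (n_syn > 0) sprintf("syn-miR-%04d", seq_len(n_syn)) else character(0)
    names_all <- c(names_named, names_syn)
    if (anyDuplicated(names_all))
      stop("duplicate mature miRNA names in generated reference")

    seqs <- character(n_mirnas)
    i_assay <- match(names_all, assay$name)
    known <- !is.na(i_assay)
    seqs[known] <- assay$sequence[i_assay[known]]
    # synthetic mature sequences, redrawn on the (unlikely) collision
    need <- which(!known)
    taken <- seqs[known]
    for (i in need) {
      for (try in 1:100) {
        s <- random_dna(sample(18:25, 1L))
        if (!(s %in% taken)) break
      }
      if (s %in% taken) stop("could not generate a unique mature sequence")
      seqs[i] <- s
      taken <- c(taken, s)
    }

    len <- nchar(seqs)
    up <- random_dna(rep(flank, n_mirnas))
    down <- random_dna(rep(flank, n_mirnas))
    hp_id <- sprintf("hp-%s", names_all)
    hairpin <- paste0(up, seqs, down)

    ref <- list(
      mature = data.frame(name = names_all, sequence = seqs,
                          hairpin_id = hp_id, start = flank,
                          end = flank + len, stringsAsFactors = FALSE),
      hairpin = data.frame(id = hp_id, sequence = hairpin,
                           stringsAsFactors = FALSE)
    )
    class(ref) <- "mirna_reference"
    validate_reference(ref)
    ref
  })
}

validate_reference <- function(ref) {
  stopifnot(inherits(ref, "mirna_reference"))
  m <- ref$mature
  h <- ref$hairpin
  if (anyDuplicated(m$name)) stop("mature names not unique")
  i <- match(m$hairpin_id, h$id)
  if (anyNA(i)) stop("mature record references unknown hairpin")
  emb <- substr(h$sequence[i], m$start + 1L, m$end)
  if (!all(emb == m$sequence))
    stop("mature sequence does not match hairpin at recorded coordinates")
  invisible(ref)
}

#' @export
print.mirna_reference <- function(x, ...) {
  cat(sprintf("mirna_reference: %d mature miRNAs on %d hairpins\n",
              nrow(x$mature), nrow(x$hairpin)))
  invisible(x)
}

#' Write a miRNA reference to FASTA plus coordinate sidecar
#'
#' Emits \code{mature.fa}, \code{hairpin.fa} and \code{coords.tsv}
#' (hairpin_id, mature_name, start, end; 0-based half-open) into \code{dir}.
#'
#' @param ref a \code{mirna_reference}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_reference <- function(ref, dir) {
  validate_reference(ref)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- Biostrings::DNAStringSet(ref$mature$sequence)
  names(mat) <- ref$mature$name
  hp <- Biostrings::DNAStringSet(ref$hairpin$sequence)
  names(hp) <- ref$hairpin$id
  Biostrings::writeXStringSet(mat, file.path(dir, "mature.fa"))
  Biostrings::writeXStringSet(hp, file.path(dir, "hairpin.fa"))
  coords <- data.frame(hairpin_id = ref$mature$hairpin_id,
                       mature_name = ref$mature$name,
                       start = ref$mature$start, end = ref$mature$end)
  utils::write.table(coords, file.path(dir, "coords.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a miRNA reference written by \code{\link{write_reference}}
#'
#' @param dir directory containing \code{mature.fa}, \code{hairpin.fa},
#'   \code{coords.tsv}.
#' @return A \code{mirna_reference}.
#' @export
read_reference <- function(dir) {
  mat <- Biostrings::readDNAStringSet(file.path(dir, "mature.fa"))
  hp <- Biostrings::readDNAStringSet(file.path(dir, "hairpin.fa"))
  coords <- utils::read.delim(file.path(dir, "coords.tsv"),
                              stringsAsFactors = FALSE)
  i <- match(names(mat), coords$mature_name)
  if (anyNA(i)) stop("coords.tsv does not cover every mature sequence")
  ref <- list(
    mature = data.frame(name = names(mat),
                        sequence = unname(as.character(mat)),
                        hairpin_id = coords$hairpin_id[i],
                        start = coords$start[i], end = coords$end[i],
                        row.names = NULL, stringsAsFactors = FALSE),
    hairpin = data.frame(id = names(hp),
                         sequence = unname(as.character(hp)),
                         row.names = NULL, stringsAsFactors = FALSE)
  )
  class(ref) <- "mirna_reference"
  validate_reference(ref)
  ref
}
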