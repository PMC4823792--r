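#' Formal side-chain charge profile of a protein sequence
#'
#' Simple pH-7.4 formal-charge bookkeeping: Asp and Glu side chains count
#' -1, Lys and Arg +1. Histidine (side-chain pKa ~ 6) is neutral by
#' default and counts +1 only when \code{count_his_positive = TRUE}.
#' Termini contribute +1 (N) and -1 (C) when \code{include_termini}.
#'
#' @param sequence one-letter amino-acid string (20-letter alphabet).
#' @param pH stated pH (bookkeeping metadata; charges are formal, not
#'   Henderson-Hasselbalch fractions).
#' @param count_his_positive treat His as +1.
#' @param include_termini add the terminal charges.
#' @return object of class \code{charge_profile}: \code{sequence},
#'   \code{per_residue} (integer vector), \code{n_negative},
#'   \code{n_positive}, \code{net_charge}, \code{termini_included},
#'   \code{pH}.
#' @export
charge_profile <- function(sequence, pH = 7.4, count_his_positive = FALSE,
                           include_termini = FALSE) {
  sequence <- toupper(gsub("\\s", "", sequence))
  aa <- strsplit(sequence, "")[[1]]
  alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V")
  bad <- which(!aa %in% alphabet)
  if (length(bad))
    stop_data("unknown residue letter '", aa[bad[1L]], "' at position ",
              bad[1L])
  charge <- integer(length(aa))
  charge[aa %in% c("D", "E")] <- -1L
  charge[aa %in% c("K", "R")] <- +1L
  if (count_his_positive) charge[aa == "H"] <- +1L
  n_neg <- sum(charge < 0L)
  n_pos <- sum(charge > 0L)
  # termini (+1 amino, -1 carboxyl) cancel in the net for a whole chain
  net <- sum(charge) + if (include_termini && length(aa)) 1L - 1L else 0L
  structure(list(sequence = sequence, per_residue = charge,
                 n_negative = n_neg, n_positive = n_pos,
                 net_charge = net, termini_included = include_termini,
                 pH = pH), class = "charge_profile")
}

#' @export
print.charge_profile <- function(x, ...) {
  cat("<charge_profile> ", nchar(x$sequence), " aa at pH ", x$pH, ": ",
      x$n_negative, " negative, ", x$n_positive, " positive, net ",
      sprintf("%+d", x$net_charge),
      if (x$termini_included) " (termini included)", "\n", sep = "")
  invisible(x)
}

#' Extract a subsequence by 1-based inclusive residue range
#'
#' @param sequence amino-acid string.
#' @param start,end 1-based inclusive bounds.
#' @return the subsequence (length \code{end - start + 1}).
#' @export
subsequence <- function(sequence, start, end) {
  n <- nchar(sequence)
  if (start < 1L || end > n || start > end)
    stop_usage("range ", start, ":", end, " out of bounds for length ", n)
  substr(sequence, start, end)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers around \pkg{seqinr}'s FASTA IO returning plain uppercase
#' strings; sequences round-trip exactly.
#'
#' @param path file path.
#' @return \code{read_fasta}: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_data("no such FASTA file: ", path)
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  toupper(unlist(seqs))
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  seqinr::write.fasta(as.list(unname(sequences)), names(sequences), path)
  invisible(path)
}

#' Bundled SNAP25B sequence
#'
#' The 206-residue rat SNAP25B sequence shipped with the package
#' (\code{inst/extdata/snap25b_rat.fasta}), the model negatively charged
#' membrane protein of the analyses.
#'
#' @return single character string.
#' @export
snap25b_sequence <- function() {
  unname(read_fasta(system.file("extdata", "snap25b_rat.fasta",
                                package = "ionbridge", mustWork = TRUE))[1L])
}

#' Bundled ion property table
#'
#' Literature values for the cations (and reference anion) used in
#' ion-specificity comparisons: charge, Shannon effective ionic radius
#' (6-coordinate, Angstrom), Jones-Dole viscosity B coefficient
#' (cm^3/mol), hydration free energy (kJ/mol, Marcus 1991) and typical
#' first-shell coordination number.
#'
#' @return data.frame, one row per ion.
#' @export
ion_properties <- function() {
  read.csv(system.file("extdata", "ion_properties.csv",
                       package = "ionbridge", mustWork = TRUE),
           comment.char = "#", stringsAsFactors = FALSE)
}

#' Ion charge-to-radius ratio
#'
#' The electrostatic surface-field proxy used to order cations by their
#' clustering efficacy: formal charge divided by crystal (ionic) radius.
#'
#' @param ion one row of \code{\link{ion_properties}} (or any list with
#'   \code{charge} and \code{crystal_radius_A}).
#' @return ratio in e/Angstrom.
#' @export
charge_to_radius <- function(ion) {
  if (is.data.frame(ion) && nrow(ion) > 1L)
    return(vapply(seq_len(nrow(ion)), function(i) charge_to_radius(ion[i, ]),
                  numeric(1)))
  r <- as.numeric(ion$crystal_radius_A)
  if (is.na(r) || r <= 0) stop_usage("crystal radius must be positive")
  as.numeric(ion$charge) / r
}

#' Hydration-energy-per-coordination ratio
#'
#' Negative hydration free energy divided by coordination number, the
#' water-release cost proxy (kJ/mol per first-shell water).
#'
#' @inheritParams charge_to_radius
#' @return ratio in kJ/mol.
#' @export
hydration_per_coordination <- function(ion) {
  if (is.data.frame(ion) && nrow(ion) > 1L)
    return(vapply(seq_len(nrow(ion)),
                  function(i) hydration_per_coordination(ion[i, ]),
                  numeric(1)))
  -as.numeric(ion$hydration_energy_kJ_mol) /
    as.numeric(ion$coordination_number)
}
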