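#' Classify a peptide sequence into hydropathy classes
#'
#' Accepts a one-letter string (split into characters) or a character
#' vector of tokens (e.g. three-letter codes, including non-natural
#' residues such as `ADA`). Every token must be present in the class
#' table -- design checks should not silently classify unknown residues.
#'
#' @param sequence character scalar (one-letter string) or character vector
#'   of residue tokens.
#' @param class_table a [read_class_table()] object.
#' @return An object of class `sequence_pattern`: list with `tokens`,
#'   `classes` (character vector over hydrophobic/polar/charged_pos/
#'   charged_neg/other) and `length`.
#' @export
classify_sequence <- function(sequence, class_table = default_class_table()) {
  if (length(sequence) == 1 && !sequence %in% names(class_table$residues)) {
    tokens <- strsplit(sequence, "")[[1]]
  } else {
    tokens <- as.character(sequence)
  }
  classes <- character(length(tokens))
  for (k in seq_along(tokens)) {
    hit <- class_table$residues[[tokens[k]]]
    if (is.null(hit)) {
      stop("unknown residue token '", tokens[k], "' at position ", k,
           call. = FALSE)
    }
    classes[k] <- hit$class
  }
  structure(list(tokens = tokens, classes = classes,
                 length = length(tokens)),
            class = "sequence_pattern")
}

#' @export
print.sequence_pattern <- function(x, ...) {
  sym <- c(hydrophobic = "H", polar = "P", charged_pos = "+",
           charged_neg = "-", other = "?")
  cat("sequence_pattern (", x$length, " residues): ",
      paste(sym[x$classes], collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Hydrophobic/hydrophilic alternation score
#'
#' Fraction of adjacent residue pairs whose hydrophobic vs non-hydrophobic
#' status differs (charged residues count as hydrophilic). 1 for perfect
#' alternation, 0 for a homopolymer-like pattern.
#'
#' @param pattern a [classify_sequence()] result.
#' @return fraction in [0, 1].
#' @export
alternation_score <- function(pattern) {
  if (pattern$length < 2) {
    stop("alternation score requires at least 2 residues", call. = FALSE)
  }
  hyd <- pattern$classes == "hydrophobic"
  mean(hyd[-length(hyd)] != hyd[-1])
}

#' Design rules for beta-amphipathic detergent peptides
#'
#' Encodes the heuristics for short membrane-protein-solubilizing
#' beta peptides: a length matched to the bilayer width (12 residues),
#' strict hydrophobic/hydrophilic alternation to make the strand
#' amphipathic, positive charge in the N-terminal half complemented by
#' negative charge in the C-terminal half (favouring antiparallel
#' pairing), and zero net charge.
#'
#' @param target_length required length (residues).
#' @param min_alternation minimum [alternation_score()].
#' @param require_terminal_charge_complementarity require N-half net
#'   charge > 0 and C-half net charge < 0.
#' @param require_net_neutrality require zero net charge.
#' @return list of class `design_rules`.
#' @export
design_rules <- function(target_length = 12, min_alternation = 0.8,
                         require_terminal_charge_complementarity = TRUE,
                         require_net_neutrality = TRUE) {
  structure(list(
    target_length = as.integer(target_length),
    min_alternation = min_alternation,
    require_terminal_charge_complementarity =
      isTRUE(require_terminal_charge_complementarity),
    require_net_neutrality = isTRUE(require_net_neutrality)
  ), class = "design_rules")
}

#' Check a sequence pattern against the amphipathic design rules
#'
#' The "N-terminal part" is the first ceiling(L/2) residues and the
#' "C-terminal part" the remaining floor(L/2). Charge is +1 per
#' `charged_pos` and -1 per `charged_neg` residue.
#'
#' @param pattern a [classify_sequence()] result.
#' @param rules a [design_rules()] object.
#' @return An object of class `design_report`: list with per-rule booleans
#'   (`length_ok`, `alternation_ok`, `terminal_charge_ok`, `neutrality_ok`,
#'   `all_ok`) and the counts behind them (`length`, `alternation`,
#'   `net_charge`, `n_half_charge`, `c_half_charge`).
#' @export
design_check <- function(pattern, rules = design_rules()) {
  L <- pattern$length
  charge <- (pattern$classes == "charged_pos") -
    (pattern$classes == "charged_neg")
  n_half <- seq_len(ceiling(L / 2))
  c_half <- setdiff(seq_len(L), n_half)
  alt <- if (L >= 2) alternation_score(pattern) else NA_real_
  rep <- list(
    length = L,
    alternation = alt,
    net_charge = sum(charge),
    n_half_charge = sum(charge[n_half]),
    c_half_charge = sum(charge[c_half]),
    length_ok = L == rules$target_length,
    alternation_ok = !is.na(alt) && alt >= rules$min_alternation,
    terminal_charge_ok = !rules$require_terminal_charge_complementarity ||
      (sum(charge[n_half]) > 0 && sum(charge[c_half]) < 0),
    neutrality_ok = !rules$require_net_neutrality || sum(charge) == 0
  )
  rep$all_ok <- rep$length_ok && rep$alternation_ok &&
    rep$terminal_charge_ok && rep$neutrality_ok
  structure(rep, class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  ok <- function(b) if (b) "PASS" else "FAIL"
  cat(sprintf("length        %-4s (%d residues)\n", ok(x$length_ok), x$length))
  cat(sprintf("alternation   %-4s (score %.2f)\n", ok(x$alternation_ok),
              x$alternation))
  cat(sprintf("term. charges %-4s (N-half %+d, C-half %+d)\n",
              ok(x$terminal_charge_ok), x$n_half_charge, x$c_half_charge))
  cat(sprintf("neutrality    %-4s (net %+d)\n", ok(x$neutrality_ok),
              x$net_charge))
  cat(sprintf("overall       %s\n", ok(x$all_ok)))
  invisible(x)
}

#' Read sequences from FASTA or plain text
#'
#' FASTA files (first non-blank character `>`) are parsed with seqinr-free
#' base code: headers become names. Plain files contribute one sequence per
#' non-empty line.
#'
#' @param path input file.
#' @return named character vector of sequences.
#' @export
read_sequences <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no sequences in ", path, call. = FALSE)
  if (startsWith(trimws(lines[1]), ">")) {
    hdr <- grepl("^>", lines)
    id <- cumsum(hdr)
    names_ <- sub("^>\\s*", "", lines[hdr])
    seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, "", collapse = "")
    setNames(gsub("\\s", "", seqs), names_)
  } else {
    s <- gsub("\\s", "", lines)
    setNames(s, paste0("seq", seq_along(s)))
  }
}

#' Run the design checks over a set of sequences and write a TSV report
#'
#' @param sequences named character vector (see [read_sequences()]).
#' @param rules a [design_rules()] object.
#' @param class_table a class table.
#' @param path output TSV, or NULL to skip writing.
#' @return data.frame with one row per sequence (invisibly if written).
#' @export
design_report_tsv <- function(sequences, rules = design_rules(),
                              class_table = default_class_table(),
                              path = NULL) {
  rows <- lapply(seq_along(sequences), function(k) {
    p <- classify_sequence(sequences[[k]], class_table)
    r <- design_check(p, rules)
    data.frame(name = names(sequences)[k], length = r$length,
               alternation = sprintf("%.3f", r$alternation),
               net_charge = r$net_charge,
               n_half_charge = r$n_half_charge,
               c_half_charge = r$c_half_charge,
               length_ok = r$length_ok, alternation_ok = r$alternation_ok,
               terminal_charge_ok = r$terminal_charge_ok,
               neutrality_ok = r$neutrality_ok, all_ok = r$all_ok)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
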