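#' Packaged domain table for the seesaw leak study
#'
#' The reusable sequence domains of the nine-oligo seesaw system: the 3-nt
#' toehold `T`, four 15-nt recognition domains `s1`--`s4`, and the 1-nt
#' spacer `Tsp` ("T") used by repeat tokens such as `15T` to build the
#' poly-T hairpin loop. `Tsp` is deliberately distinct from the toehold
#' domain `T`: the two share a letter in formula notation but not a role.
#'
#' @return A data.frame with columns `name`, `kind`
#'   (`toehold`/`recognition`/`spacer`) and `sequence` (5'->3').
#' @export
#' @examples
#' seesaw_domains()
seesaw_domains <- function() {
  data.frame(
    name = c("T", "s1", "s2", "s3", "s4", "Tsp"),
    kind = c("toehold", rep("recognition", 4L), "spacer"),
    sequence = c(
      "TCT",
      "CACCCTAAAATCTCA",
      "CACCACCAAACTTCA",
      "CACTAACATACAACA",
      "CAACATATCAATTCA",
      "T"
    ),
    stringsAsFactors = FALSE
  )
}

#' Packaged strand table (P1--P9)
#'
#' The nine oligonucleotides of the seesaw leak study, each with its
#' domain formula and its printed 5'->3' sequence. Hyphens and whitespace
#' in printed sequences are presentation only and are stripped.
#'
#' Note that P5's declared formula (`T' + s2' + T`) assembles to a sequence
#' whose final three nucleotides (`TCT`) differ from the printed tail
#' (`AGA`, the reverse complement); [validate_strand()] reports this
#' discrepancy rather than silently correcting either side.
#'
#' @return A data.frame with columns `name`, `formula`, `printed`.
#' @export
seesaw_strands <- function() {
  out <- data.frame(
    name = paste0("P", 1:9),
    formula = c(
      "s2 + T + s1",
      "s2",
      "T' + s2'",
      "s3 + T + s2",
      "T' + s2' + T",
      "s4 + T + s2",
      "T' + s3'",
      "s3",
      "T' + s3' + 15T + s3"
    ),
    printed = c(
      "CACCACCAAACTTCATCTCACCCTAAAATCTCA",
      "CACCACCAAACTTCA",
      "AGATGAAGTTTGGTGGTG",
      "CACTAACATACAACATCTCACCACCAAACTTCA",
      "AGATGAAGTTTGGTGGTGAGA",
      "CAACATATCAATTCATCTCACCACCAAACTTCA",
      "AGATGTTGTATGTTAGTG",
      "CACTAACATACAACA",
      "AGATGTTGTATGTTAGTG-TTTTTTTTTTTTTTT-CACTAACATACAACA"
    ),
    stringsAsFactors = FALSE
  )
  out$printed <- vapply(out$printed, clean_seq, character(1), USE.NAMES = FALSE)
  out
}

#' Packaged component samples (T1--T6)
#'
#' The functional complexes of the seesaw system and the strands forming
#' each: Input (T1), Threshold (T2), Gate (T3), Fuel (T4), the
#' fluorophore/quencher Reporter duplex (T5) and the hairpin Reporter (T6).
#' Sample ids live in a namespace separate from domain names, so sample
#' `T1` never collides with the toehold domain `T`.
#'
#' @return A data.frame with columns `sample_id`, `role`, and a list
#'   column `strands` of strand-name character vectors.
#' @export
seesaw_complexes <- function() {
  data.frame(
    sample_id = paste0("T", 1:6),
    role = c("Input", "Threshold", "Gate", "Fuel", "Reporter", "Reporter"),
    strands = I(list("P1", c("P2", "P3"), c("P4", "P5"), "P6",
                     c("P7", "P8"), "P9")),
    stringsAsFactors = FALSE
  )
}

# strip presentation hyphens/whitespace and uppercase
clean_seq <- function(x) {
  toupper(gsub("[-[:space:]]", "", x))
}

check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  bad <- gregexpr("[^ACGT]", x)[[1]]
  if (bad[1] != -1L)
    stop(what, " contains non-ACGT character(s) at 0-based position(s) ",
         paste(bad - 1L, collapse = ", "), call. = FALSE)
  invisible(x)
}

#' Reverse complement of a DNA sequence
#'
#' Strict reverse complement over the `{A,C,G,T}` alphabet, 5'->3' in and
#' out. Non-ACGT characters are rejected with their 0-based positions.
#'
#' @param x Character vector of DNA sequences (each 5'->3', ACGT only;
#'   the empty string is allowed and maps to itself).
#' @return Character vector of reverse complements, 5'->3'.
#' @export
#' @examples
#' revcomp("CACCACCAAACTTCATCT")  # the printed P3 sequence
#' revcomp(revcomp("ACGT")) == "ACGT"
revcomp <- function(x) {
  vapply(x, function(s) {
    check_dna(s)
    if (nchar(s) == 0L) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Parse a domain formula
#'
#' Formulas are `+`-separated tokens such as `"T' + s3' + 15T + s3"`.
#' Each token is an optional repeat count, a domain name, and an optional
#' prime mark (`'` or the typographic prime) meaning reverse complement.
#' A repeat-count token written on `T` (e.g. `15T`) refers to the 1-nt
#' spacer domain `Tsp`, not the toehold: the poly-T loop notation.
#'
#' @param formula A single formula string.
#' @return A data.frame with columns `domain`, `primed` (logical),
#'   `times` (integer repeat count, >= 1).
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula))
    stop("formula must be a single character string", call. = FALSE)
  toks <- trimws(strsplit(formula, "+", fixed = TRUE)[[1]])
  if (length(toks) == 0L || any(toks == ""))
    stop("empty token in formula: ", formula, call. = FALSE)
  m <- regmatches(toks, regexec("^([0-9]*)([A-Za-z][A-Za-z0-9]*)(['′]?)$", toks))
  parsed <- lapply(seq_along(toks), function(k) {
    g <- m[[k]]
    if (length(g) == 0L)
      stop("cannot parse token '", toks[k], "' in formula: ", formula,
           call. = FALSE)
    times <- if (g[2] == "") 1L else as.integer(g[2])
    if (times < 1L)
      stop("repeat count must be >= 1 in token '", toks[k], "'", call. = FALSE)
    dom <- g[3]
    if (times > 1L && dom == "T") dom <- "Tsp"
    data.frame(domain = dom, primed = g[4] != "", times = times,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, parsed)
}

#' Assemble a strand sequence from its domain formula
#'
#' Concatenates token contributions in listed order, 5'->3': an unprimed
#' token contributes its domain sequence, a primed token `X'` contributes
#' `revcomp(X)`, and a repeat token contributes the domain repeated.
#'
#' @param formula Formula string or pre-parsed token data.frame
#'   (see [parse_formula()]).
#' @param domains Domain table; defaults to [seesaw_domains()].
#' @return The assembled DNA sequence (character scalar).
#' @export
#' @examples
#' assemble_strand("s2 + T + s1")  # the P1 sequence
assemble_strand <- function(formula, domains = seesaw_domains()) {
  toks <- if (is.data.frame(formula)) formula else parse_formula(formula)
  idx <- match(toks$domain, domains$name)
  if (anyNA(idx))
    stop("unknown domain name(s): ",
         paste(unique(toks$domain[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  pieces <- mapply(function(i, primed, times) {
    s <- strrep(domains$sequence[i], times)
    if (primed) revcomp(s) else s
  }, idx, toks$primed, toks$times)
  paste(pieces, collapse = "")
}

#' Validate a strand's printed sequence against its domain formula
#'
#' Assembles the formula and compares it with the printed sequence
#' character by character. Length mismatches are a distinct failure class;
#' equal-length mismatches are reported with their 0-based positions.
#'
#' @param name Strand name (e.g. `"P5"`), or a one-row data.frame with
#'   `name`, `formula`, `printed` columns.
#' @param strands Strand table; defaults to [seesaw_strands()].
#' @param domains Domain table; defaults to [seesaw_domains()].
#' @return A list with elements `name`, `assembled`, `printed`, `match`,
#'   `length_match`, `mismatch_positions` (0-based integer vector, empty
#'   on match or length mismatch).
#' @export
#' @examples
#' validate_strand("P1")$match   # TRUE
#' validate_strand("P5")$mismatch_positions  # 18 19 20
validate_strand <- function(name, strands = seesaw_strands(),
                            domains = seesaw_domains()) {
  row <- if (is.data.frame(name)) name else {
    i <- match(name, strands$name)
    if (is.na(i)) stop("unknown strand: ", name, call. = FALSE)
    strands[i, ]
  }
  assembled <- assemble_strand(row$formula, domains)
  printed <- clean_seq(row$printed)
  check_dna(printed, paste0(row$name, " printed sequence"))
  length_match <- nchar(assembled) == nchar(printed)
  mism <- integer(0)
  if (length_match && assembled != printed) {
    a <- strsplit(assembled, "")[[1]]
    p <- strsplit(printed, "")[[1]]
    mism <- which(a != p) - 1L
  }
  list(name = row$name, assembled = assembled, printed = printed,
       match = identical(assembled, printed), length_match = length_match,
       mismatch_positions = mism)
}

#' Validate all packaged strands
#'
#' @inheritParams validate_strand
#' @return A data.frame with one row per strand: `name`, `match`,
#'   `length_match`, `n_mismatch`, and list column `mismatch_positions`.
#' @export
validate_strands <- function(strands = seesaw_strands(),
                             domains = seesaw_domains()) {
  reps <- lapply(seq_len(nrow(strands)), function(i)
    validate_strand(strands[i, ], strands, domains))
  data.frame(
    name = vapply(reps, `[[`, character(1), "name"),
    match = vapply(reps, `[[`, logical(1), "match"),
    length_match = vapply(reps, `[[`, logical(1), "length_match"),
    n_mismatch = vapply(reps, function(r) length(r$mismatch_positions),
                        integer(1)),
    mismatch_positions = I(lapply(reps, `[[`, "mismatch_positions")),
    stringsAsFactors = FALSE
  )
}

# maximal equal substrings between a and b, as rows of
# (0-based start in a, 0-based start in b, length), length >= min_len
lcs_runs <- function(a, b, min_len) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  if (na == 0L || nb == 0L) return(NULL)
  eq <- outer(av, bv, "==")
  runs <- NULL
  for (d in (-(na - 1L)):(nb - 1L)) {
    i0 <- max(1L, 1L - d)
    diag_len <- min(na - i0, nb - (i0 + d)) + 1L
    ii <- i0 + seq_len(diag_len) - 1L
    hits <- eq[cbind(ii, ii + d)]
    r <- rle(hits)
    ends <- cumsum(r$lengths)
    for (k in which(r$values & r$lengths >= min_len)) {
      start_i <- ii[ends[k] - r$lengths[k] + 1L]
      runs <- rbind(runs, c(start_i - 1L, start_i + d - 1L, r$lengths[k]))
    }
  }
  runs
}

#' Duplex map of a component complex
#'
#' Finds the maximal exactly complementary paired regions between the two
#' strands of a complex by scanning one strand against the reverse
#' complement of the other. Single-strand complexes return an empty map;
#' two-strand complexes with no complementary region of at least
#' `min_len` nt return an empty map with a warning.
#'
#' Intervals are 0-based, half-open, on each strand's own 5'->3'
#' coordinates.
#'
#' @param sample_id Complex id (`"T1"`..`"T6"`), or a character vector of
#'   one or two strand names.
#' @param min_len Minimum paired-region length reported (nt); default 8,
#'   long enough to exclude chance complementary k-mers between 15-nt
#'   recognition domains.
#' @param strands Strand table; defaults to [seesaw_strands()] (printed
#'   sequences are used).
#' @return A data.frame with columns `strand1`, `start1`, `end1`,
#'   `strand2`, `start2`, `end2`, `length`.
#' @export
#' @examples
#' duplex_map("T3")  # the 18-bp Gate duplex, P4's s3 left single-stranded
duplex_map <- function(sample_id, min_len = 8L, strands = seesaw_strands()) {
  empty <- data.frame(strand1 = character(0), start1 = integer(0),
                      end1 = integer(0), strand2 = character(0),
                      start2 = integer(0), end2 = integer(0),
                      length = integer(0), stringsAsFactors = FALSE)
  cx <- seesaw_complexes()
  names_ <- if (length(sample_id) == 1L && sample_id %in% cx$sample_id)
    cx$strands[[match(sample_id, cx$sample_id)]] else sample_id
  if (length(names_) == 1L) return(empty)
  if (length(names_) != 2L)
    stop("duplex_map expects a complex of 1 or 2 strands", call. = FALSE)
  i <- match(names_, strands$name)
  if (anyNA(i)) stop("unknown strand(s): ",
                     paste(names_[is.na(i)], collapse = ", "), call. = FALSE)
  a <- strands$printed[i[1]]; b <- strands$printed[i[2]]
  nb <- nchar(b)
  runs <- lcs_runs(a, revcomp(b), as.integer(min_len))
  if (is.null(runs)) {
    warning("no complementary region of >= ", min_len, " nt between ",
            names_[1], " and ", names_[2])
    return(empty)
  }
  runs <- runs[order(-runs[, 3]), , drop = FALSE]
  out <- data.frame(
    strand1 = names_[1], start1 = runs[, 1], end1 = runs[, 1] + runs[, 3],
    strand2 = names_[2],
    start2 = nb - runs[, 2] - runs[, 3], end2 = nb - runs[, 2],
    length = runs[, 3], stringsAsFactors = FALSE
  )
  # re-check Watson-Crick complementarity of every reported pair
  for (k in seq_len(nrow(out))) {
    sa <- substr(a, out$start1[k] + 1L, out$end1[k])
    sb <- substr(b, out$start2[k] + 1L, out$end2[k])
    stopifnot(identical(sa, revcomp(sb)))
  }
  out
}

#' Hairpin geometry of a strand
#'
#' Derives stem/loop/toehold partitioning from the domain formula: the
#' stem is a primed/unprimed occurrence of the same non-spacer domain,
#' the loop is everything between the pair, and the toehold is the
#' residual unpaired overhang outside it. For the packaged hairpin
#' reporter P9 this gives a 15-bp stem, 15-nt poly-T loop and 3-nt
#' toehold, summing with the stem counted twice to the 48-nt sequence.
#'
#' @param name Strand name, or a one-row data.frame with `name`,
#'   `formula`, `printed`.
#' @param strands Strand table; defaults to [seesaw_strands()].
#' @param domains Domain table; defaults to [seesaw_domains()].
#' @return A list with `stem_bp`, `loop_nt`, `toehold_nt` (all >= 0);
#'   `2*stem_bp + loop_nt + toehold_nt` equals the strand length.
#' @export
#' @examples
#' hairpin_geometry("P9")
hairpin_geometry <- function(name, strands = seesaw_strands(),
                             domains = seesaw_domains()) {
  row <- if (is.data.frame(name)) name else {
    i <- match(name, strands$name)
    if (is.na(i)) stop("unknown strand: ", name, call. = FALSE)
    strands[i, ]
  }
  toks <- parse_formula(row$formula)
  idx <- match(toks$domain, domains$name)
  if (anyNA(idx)) stop("unknown domain name(s) in formula", call. = FALSE)
  toklen <- nchar(domains$sequence[idx]) * toks$times
  kinds <- domains$kind[idx]
  pair <- NULL
  for (i in seq_len(nrow(toks))) {
    for (j in seq_len(nrow(toks))) {
      if (j <= i) next
      if (toks$domain[i] == toks$domain[j] &&
          xor(toks$primed[i], toks$primed[j]) &&
          kinds[i] != "spacer") {
        pair <- c(i, j); break
      }
    }
    if (!is.null(pair)) break
  }
  if (is.null(pair))
    stop("not a hairpin: no primed/unprimed domain pair in formula '",
         row$formula, "'", call. = FALSE)
  i <- pair[1]; j <- pair[2]
  stem <- toklen[i]
  loop <- if (j - i > 1L) sum(toklen[(i + 1L):(j - 1L)]) else 0L
  toehold <- sum(toklen[-seq.int(i, j)])
  total <- nchar(clean_seq(row$printed))
  if (2L * stem + loop + toehold != total)
    stop("hairpin partition (2*", stem, " + ", loop, " + ", toehold,
         ") does not sum to strand length ", total, call. = FALSE)
  list(stem_bp = as.integer(stem), loop_nt = as.integer(loop),
       toehold_nt = as.integer(toehold))
}

#' Export packaged strands as FASTA
#'
#' @param path Output file path.
#' @param strands Strand table; defaults to [seesaw_strands()].
#' @param width Line-wrap width; default 60.
#' @return `path`, invisibly.
#' @export
export_fasta <- function(path, strands = seesaw_strands(), width = 60L) {
  set <- Biostrings::DNAStringSet(strands$printed)
  names(set) <- strands$name
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Export the domain table as delimited text
#'
#' @param path Output file path (tab-separated: name, kind, sequence).
#' @param domains Domain table; defaults to [seesaw_domains()].
#' @return `path`, invisibly.
#' @export
export_domains <- function(path, domains = seesaw_domains()) {
  utils::write.table(domains, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
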