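# Parsing and representation of stapled-peptide sequence notation.
#
# Grammar: hyphen-separated cap tokens flank a residue core, e.g.
#   "Ac-LTF[R8]EYWQL[Cba][S5]SAA-amide"
#   "Ac-K(N3)-(bA)-LTF[R8]EYWAQ[Cba][S5]SAA-amide"
# Core tokens are bare one-letter codes for natural L-amino acids or
# bracketed multi-character tokens: staple anchors [R8]/[S5], [Aib], [Cba],
# D-residues ([D-Trp]), and N-methylated residues ([NMe-A]). Positions are
# 1-based over the core; caps are unnumbered.

.AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
.AA3 <- c(A = "Ala", C = "Cys", D = "Asp", E = "Glu", F = "Phe", G = "Gly",
          H = "His", I = "Ile", K = "Lys", L = "Leu", M = "Met", N = "Asn",
          P = "Pro", Q = "Gln", R = "Arg", S = "Ser", T = "Thr", V = "Val",
          W = "Trp", Y = "Tyr")
.STAPLE_ANCHORS <- c("R8", "S5")
# unicode beta accepted on input; canonical cap renders as "(βA)"
.N_CAPS <- c("Ac", "K(N3)", "βA", "bA")
.AA_LIKE_CAPS <- c("K(N3)", "βA")

# Resolve one core token to a residue record or NULL if unknown.
.resolve_token <- function(tok) {
  res <- function(code, chir, nme = FALSE, anchor = FALSE, note = "") {
    list(code = code, chirality = chir, n_methylated = nme,
         is_staple_anchor = anchor, sidechain_note = note)
  }
  if (tok %in% .AA1) {
    return(res(tok, if (tok == "G") "achiral" else "L"))
  }
  if (tok %in% .STAPLE_ANCHORS) {
    return(res(tok, "L", anchor = TRUE,
               note = "alpha-methyl olefin staple anchor"))
  }
  if (tok == "Aib") return(res("Aib", "achiral",
                               note = "alpha-aminoisobutyric acid"))
  if (tok == "Cba") return(res("Cba", "L", note = "cyclobutylalanine"))
  if (grepl("^D-", tok)) {
    base <- sub("^D-", "", tok)
    one <- names(.AA3)[match(base, .AA3)]
    if (!is.na(one) && one != "G") return(res(paste0("D-", base), "D"))
    if (base == "Cba") return(res("D-Cba", "D", note = "cyclobutylalanine"))
    return(NULL)
  }
  if (grepl("^NMe-", tok, ignore.case = TRUE)) {
    base <- toupper(sub("^NMe-", "", tok, ignore.case = TRUE))
    if (base %in% .AA1 && base != "P") {
      return(res(paste0("NMe-", base),
                 if (base == "G") "achiral" else "L", nme = TRUE))
    }
    return(NULL)
  }
  NULL
}

# Tokenize a residue core: bare letters and [..] groups; no loose hyphens.
.tokenize_core <- function(core) {
  toks <- character(0)
  i <- 1L
  chars <- strsplit(core, "")[[1]]
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) {
        stop("parse error: unterminated '[' in residue core", call. = FALSE)
      }
      toks <- c(toks, paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L
    } else if (grepl("[A-Za-z]", ch)) {
      toks <- c(toks, ch)
      i <- i + 1L
    } else {
      stop(sprintf("parse error: unexpected character '%s' in residue core",
                   ch), call. = FALSE)
    }
  }
  toks
}

#' Parse stapled-peptide sequence notation
#'
#' Parses a notation string into a `peptide` object: N-terminal cap tokens,
#' an ordered residue core with chirality / N-methylation / staple-anchor
#' flags, the C-terminal cap, and the detected staple topology. Both staple
#' anchors (`R8` at i, `S5` at j) must be present with spacing `j - i = 7`,
#' or neither (linear peptides).
#'
#' @param notation Notation string (see the package grammar above).
#' @param name Optional peptide identifier stored on the object.
#' @return An object of class `peptide` with fields `name`, `n_cap`,
#'   `residues` (data frame: `position`, `code`, `chirality`,
#'   `n_methylated`, `is_staple_anchor`, `sidechain_note`), `c_cap`, and
#'   `staple_pair` (integer pair or `NULL`).
#' @examples
#' p <- parse_peptide("Ac-LTF[R8]EYWQL[Cba][S5]SAA-amide", name = "MP-292")
#' residue_count(p)
#' p$staple_pair
#' @export
parse_peptide <- function(notation, name = NULL) {
  if (is.null(notation) || !nzchar(trimws(notation))) {
    stop("parse error: empty notation", call. = FALSE)
  }
  s <- trimws(notation)
  c_cap <- NULL
  if (grepl("-(amide|NH2)$", s)) {
    c_cap <- "amide"
    s <- sub("-(amide|NH2)$", "", s)
  }
  n_cap <- character(0)
  repeat {
    hit <- regmatches(s, regexpr(
      "^(Ac|K\\(N3\\)|\\(?βA\\)?|\\(?bA\\)?)-", s, perl = TRUE))
    if (!length(hit)) break
    tok <- sub("-$", "", hit)
    tok <- sub("^\\((.*)\\)$", "\\1", tok)  # unwrap "(βA)" only
    if (tok == "bA") tok <- "βA"
    n_cap <- c(n_cap, tok)
    s <- substring(s, nchar(hit) + 1L)
  }
  toks <- .tokenize_core(s)
  if (!length(toks)) stop("parse error: no residues found", call. = FALSE)
  rows <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    r <- .resolve_token(toks[i])
    if (is.null(r)) {
      stop(sprintf("parse error: unknown token '%s' at position %d",
                   toks[i], i), call. = FALSE)
    }
    rows[[i]] <- r
  }
  residues <- data.frame(
    position = seq_along(rows),
    code = vapply(rows, `[[`, "", "code"),
    chirality = vapply(rows, `[[`, "", "chirality"),
    n_methylated = vapply(rows, `[[`, FALSE, "n_methylated"),
    is_staple_anchor = vapply(rows, `[[`, FALSE, "is_staple_anchor"),
    sidechain_note = vapply(rows, `[[`, "", "sidechain_note"),
    stringsAsFactors = FALSE)
  anchors <- residues$position[residues$is_staple_anchor]
  staple_pair <- NULL
  if (length(anchors) > 0) {
    if (length(anchors) != 2) {
      stop("topology error: staple requires exactly two anchors (R8, S5)",
           call. = FALSE)
    }
    if (diff(anchors) != 7) {
      stop(sprintf("topology error: staple anchors at %d/%d are not i, i+7",
                   anchors[1], anchors[2]), call. = FALSE)
    }
    if (residues$code[anchors[1]] != "R8" ||
        residues$code[anchors[2]] != "S5") {
      stop("topology error: expected R8 at i and S5 at i+7", call. = FALSE)
    }
    staple_pair <- as.integer(anchors)
  }
  structure(list(name = name, n_cap = n_cap, residues = residues,
                 c_cap = c_cap, staple_pair = staple_pair),
            class = "peptide")
}

#' Render a peptide back to canonical notation
#'
#' The canonical form uses bare one-letter codes for natural L residues and
#' bracketed tokens for everything else; `parse -> render -> parse` is the
#' identity.
#'
#' @param p A `peptide`.
#' @return Canonical notation string.
#' @export
render_peptide <- function(p) {
  stopifnot(inherits(p, "peptide"))
  cap <- if (length(p$n_cap)) {
    paste0(paste(vapply(p$n_cap, function(tok) {
      if (tok == "βA") "(βA)" else tok
    }, ""), collapse = "-"), "-")
  } else ""
  core <- paste(vapply(seq_len(nrow(p$residues)), function(i) {
    code <- p$residues$code[i]
    if (code %in% .AA1) code else paste0("[", code, "]")
  }, ""), collapse = "")
  paste0(cap, core, if (!is.null(p$c_cap)) paste0("-", p$c_cap) else "")
}

#' @export
print.peptide <- function(x, ...) {
  cat("Peptide", if (!is.null(x$name)) x$name else "", "\n")
  cat("  notation:", render_peptide(x), "\n")
  cat("  residues:", nrow(x$residues),
      if (!is.null(x$staple_pair)) {
        sprintf("(stapled %d-%d)", x$staple_pair[1], x$staple_pair[2])
      } else "(linear)", "\n")
  dres <- x$residues$position[x$residues$chirality == "D"]
  if (length(dres)) cat("  D-residues at:", paste(dres, collapse = ", "), "\n")
  nme <- x$residues$position[x$residues$n_methylated]
  if (length(nme)) cat("  N-methylated at:", paste(nme, collapse = ", "), "\n")
  invisible(x)
}

#' Count residues of a peptide
#'
#' With `include_caps = TRUE`, amino-acid-like N-cap tokens (K(N3), beta-Ala)
#' are added to the numbered core count; the acetyl cap and the C-terminal
#' amide never count. The cap-exclusive count is the default denominator for
#' mean residue ellipticity.
#'
#' @param p A `peptide`.
#' @param include_caps Count amino-acid-like cap tokens too?
#' @return Integer residue count.
#' @export
residue_count <- function(p, include_caps = FALSE) {
  stopifnot(inherits(p, "peptide"))
  n <- nrow(p$residues)
  if (include_caps) n <- n + sum(p$n_cap %in% .AA_LIKE_CAPS)
  as.integer(n)
}

#' Classify a residue position
#'
#' Positions are classified as `"staple"` (the staple anchor pair),
#' `"interfacial"` (the Mdm2-binding hot-spot positions, default 3 / 7 / 10:
#' Phe, Trp and cyclobutylalanine), or `"non-interfacial"`.
#'
#' @param p A `peptide`.
#' @param position 1-based residue position.
#' @param interfacial Integer vector of interfacial positions (configurable;
#'   defaults to `c(3, 7, 10)`).
#' @return One of `"interfacial"`, `"non-interfacial"`, `"staple"`.
#' @export
classify_position <- function(p, position, interfacial = c(3, 7, 10)) {
  stopifnot(inherits(p, "peptide"))
  if (position < 1 || position > nrow(p$residues)) {
    stop(sprintf("position %d out of range 1..%d", position,
                 nrow(p$residues)), call. = FALSE)
  }
  if (!is.null(p$staple_pair) && position %in% p$staple_pair) return("staple")
  if (position %in% interfacial) return("interfacial")
  "non-interfacial"
}

# --- scan-label lint ---------------------------------------------------------

# Parse a scan label like "F3A", "L1(D-Leu)", "S12(Aib)", "T2(NMe-Thr)" into
# (original one-letter code, position, replacement canonical code). Returns
# NULL for labels that do not follow the scan grammar (e.g. plain MP ids).
.parse_scan_label <- function(label) {
  m <- regmatches(label,
                  regexec("^([A-Z][a-z]*)(\\d+)\\(?([^)]*)\\)?$", label))[[1]]
  if (length(m) != 4 || !nzchar(m[4])) return(NULL)
  rep_tok <- m[4]
  rep_code <- if (rep_tok %in% .AA1) rep_tok
  else if (rep_tok %in% c("Aib", "Cba")) rep_tok
  else if (grepl("^D-", rep_tok)) rep_tok
  else if (grepl("^N-?[Mm]e", rep_tok)) {
    base <- sub("^N-?[Mm]e(thyl)?[ -]*", "", rep_tok)
    base <- sub("^L-", "", base)
    one <- if (base %in% .AA1) base else names(.AA3)[match(base, .AA3)]
    if (is.na(one)) return(NULL)
    paste0("NMe-", one)
  } else return(NULL)
  list(orig = m[2], position = as.integer(m[3]), replacement = rep_code)
}

#' Check a substitution-scan label against the parsed sequence
#'
#' Scan labels name the substituted position (e.g. `F3A`: Phe3 to Ala). This
#' lint verifies that the residue found at the labeled position actually is
#' the named replacement; a mismatch (the label naming one position while the
#' substitution sits at another) is reported, not corrected -- the parser
#' always trusts the sequence columns.
#'
#' @param label Scan label string; comma-separated multi-substitution labels
#'   are checked element-wise.
#' @param p The parsed variant `peptide`.
#' @return A data frame with one row per parseable label element: `label`,
#'   `position`, `expected`, `found`, `ok`, and `found_at` (positions where
#'   the replacement actually occurs when misplaced). Zero rows when the
#'   label does not follow the scan grammar.
#' @export
lint_scan_label <- function(label, p) {
  stopifnot(inherits(p, "peptide"))
  parts <- trimws(strsplit(label, ",")[[1]])
  out <- list()
  for (part in parts) {
    pl <- .parse_scan_label(part)
    if (is.null(pl)) next
    pos <- pl$position
    found <- if (pos >= 1 && pos <= nrow(p$residues)) {
      p$residues$code[pos]
    } else NA_character_
    ok <- identical(found, pl$replacement)
    found_at <- p$residues$position[p$residues$code == pl$replacement]
    out[[length(out) + 1L]] <- data.frame(
      label = part, position = pos, expected = pl$replacement,
      found = found, ok = ok,
      found_at = paste(found_at, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(label = character(0), position = integer(0),
                      expected = character(0), found = character(0),
                      ok = logical(0), found_at = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
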