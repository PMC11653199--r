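# Pauli-string algebra on up to 60 qubits.
#
# A Pauli word is stored in symplectic form as four non-negative integers:
# x1/z1 carry qubits 0..29 and x2/z2 carry qubits 30..59 (one bit per qubit).
# A set bit in x means the word acts with X on that qubit, in z with Z, in
# both with Y. The stored coefficient multiplies the literal I/X/Y/Z tensor,
# so an operator is Hermitian iff all coefficients are real.

.lut16 <- {
  v <- 0:65535L
  p <- integer(65536L)
  for (b in 0:15) p <- p + bitwAnd(bitwShiftR(v, b), 1L)
  p
}

# population count for integers in [0, 2^30)
.popcount <- function(v) {
  .lut16[bitwAnd(v, 65535L) + 1L] + .lut16[bitwShiftR(v, 16L) + 1L]
}

.word_key <- function(x1, x2, z1, z2) paste(x1, x2, z1, z2, sep = ".")

#' Construct a qubit operator from Pauli-word strings
#'
#' A word string is a space-separated list of single-qubit factors such as
#' `"X0 Y3 Z5"`; the empty string (or `"I"`) denotes the identity word.
#' Duplicate words are merged by summing coefficients.
#'
#' @param n_qubits number of qubits (<= 60).
#' @param words character vector of Pauli words.
#' @param coef complex (or numeric) coefficients, one per word.
#' @return an object of class `qubit_operator`.
#' @examples
#' qop(2, c("Z0", "Z0 Z1", "X0 X1"), c(0.3, -0.1, 0.5))
#' @export
qop <- function(n_qubits, words = character(), coef = complex()) {
  stopifnot(n_qubits >= 1, n_qubits <= 60, length(words) == length(coef))
  x1 <- x2 <- z1 <- z2 <- integer(length(words))
  for (i in seq_along(words)) {
    b <- .parse_word(words[[i]], n_qubits)
    x1[i] <- b[1L]; x2[i] <- b[2L]; z1[i] <- b[3L]; z2[i] <- b[4L]
  }
  qop_collect(new_qop(n_qubits, x1, x2, z1, z2, as.complex(coef)))
}

new_qop <- function(n_qubits, x1, x2, z1, z2, coef) {
  structure(list(n_qubits = as.integer(n_qubits),
                 x1 = as.integer(x1), x2 = as.integer(x2),
                 z1 = as.integer(z1), z2 = as.integer(z2),
                 coef = as.complex(coef)),
            class = "qubit_operator")
}

.parse_word <- function(w, n_qubits) {
  x1 <- x2 <- z1 <- z2 <- 0L
  w <- trimws(w)
  if (nzchar(w) && w != "I") {
    for (tok in strsplit(w, "\\s+")[[1]]) {
      letter <- substr(tok, 1, 1)
      q <- suppressWarnings(as.integer(substring(tok, 2)))
      if (is.na(q) || q < 0 || q >= n_qubits || !letter %in% c("X", "Y", "Z")) {
        stop("malformed Pauli factor: '", tok, "'")
      }
      if (q < 30) {
        bit <- bitwShiftL(1L, q)
        if (letter %in% c("X", "Y")) x1 <- bitwOr(x1, bit)
        if (letter %in% c("Z", "Y")) z1 <- bitwOr(z1, bit)
      } else {
        bit <- bitwShiftL(1L, q - 30L)
        if (letter %in% c("X", "Y")) x2 <- bitwOr(x2, bit)
        if (letter %in% c("Z", "Y")) z2 <- bitwOr(z2, bit)
      }
    }
  }
  c(x1, x2, z1, z2)
}

.format_word <- function(x1, x2, z1, z2, n_qubits) {
  if (x1 == 0L && x2 == 0L && z1 == 0L && z2 == 0L) return("I")
  out <- character(0)
  for (q in seq_len(n_qubits) - 1L) {
    if (q < 30) { xb <- bitwAnd(bitwShiftR(x1, q), 1L); zb <- bitwAnd(bitwShiftR(z1, q), 1L) }
    else        { xb <- bitwAnd(bitwShiftR(x2, q - 30L), 1L); zb <- bitwAnd(bitwShiftR(z2, q - 30L), 1L) }
    if (xb == 1L && zb == 1L) out <- c(out, paste0("Y", q))
    else if (xb == 1L)        out <- c(out, paste0("X", q))
    else if (zb == 1L)        out <- c(out, paste0("Z", q))
  }
  paste(out, collapse = " ")
}

#' @export
print.qubit_operator <- function(x, max_terms = 12L, ...) {
  cat(sprintf("<qubit_operator: %d qubits, %d terms>\n",
              x$n_qubits, length(x$coef)))
  n <- min(length(x$coef), max_terms)
  for (i in seq_len(n)) {
    cat(sprintf("  %s  %s\n", format(x$coef[i], digits = 8),
                .format_word(x$x1[i], x$x2[i], x$z1[i], x$z2[i], x$n_qubits)))
  }
  if (length(x$coef) > n) cat(sprintf("  ... %d more\n", length(x$coef) - n))
  invisible(x)
}

#' Merge duplicate Pauli words and drop negligible coefficients
#'
#' @param op a `qubit_operator`.
#' @param tol coefficients with modulus below `tol` are removed after
#'   merging (default 1e-12, chosen to stabilize term counting).
#' @return a `qubit_operator` with distinct words.
#' @export
qop_collect <- function(op, tol = 1e-12) {
  if (length(op$coef) == 0) return(op)
  key <- .word_key(op$x1, op$x2, op$z1, op$z2)
  f <- factor(key, levels = unique(key))
  re <- rowsum(Re(op$coef), f, reorder = FALSE)[, 1]
  im <- rowsum(Im(op$coef), f, reorder = FALSE)[, 1]
  idx <- match(levels(f), key)
  keep <- sqrt(re^2 + im^2) > tol
  new_qop(op$n_qubits, op$x1[idx][keep], op$x2[idx][keep],
          op$z1[idx][keep], op$z2[idx][keep], complex(real = re[keep], imaginary = im[keep]))
}

#' Sum of two qubit operators
#' @param a,b `qubit_operator`s on the same number of qubits.
#' @param tol pruning tolerance passed to [qop_collect()].
#' @export
qop_add <- function(a, b, tol = 1e-12) {
  stopifnot(a$n_qubits == b$n_qubits)
  qop_collect(new_qop(a$n_qubits, c(a$x1, b$x1), c(a$x2, b$x2),
                      c(a$z1, b$z1), c(a$z2, b$z2), c(a$coef, b$coef)), tol)
}

#' Scale a qubit operator by a scalar
#' @param op a `qubit_operator`; @param s scalar factor.
#' @export
qop_scale <- function(op, s) { op$coef <- op$coef * s; op }

# vectorized symplectic product of Pauli words (recycles a against b):
# returns the words and coefficients of (a_i * b_i)
.pmul <- function(ax1, ax2, az1, az2, ac, bx1, bx2, bz1, bz2, bc) {
  cx1 <- bitwXor(ax1, bx1); cx2 <- bitwXor(ax2, bx2)
  cz1 <- bitwXor(az1, bz1); cz2 <- bitwXor(az2, bz2)
  nya <- .popcount(bitwAnd(ax1, az1)) + .popcount(bitwAnd(ax2, az2))
  nyb <- .popcount(bitwAnd(bx1, bz1)) + .popcount(bitwAnd(bx2, bz2))
  nyc <- .popcount(bitwAnd(cx1, cz1)) + .popcount(bitwAnd(cx2, cz2))
  swap <- .popcount(bitwAnd(az1, bx1)) + .popcount(bitwAnd(az2, bx2))
  ph <- ((nya + nyb - nyc) %% 4L + 4L) %% 4L
  phase <- c(1 + 0i, 1i, -1 + 0i, -1i)[ph + 1L]
  sgn <- 1 - 2 * (swap %% 2L)
  list(x1 = cx1, x2 = cx2, z1 = cz1, z2 = cz2, coef = ac * bc * sgn * phase)
}

#' Product of two qubit operators
#' @param a,b `qubit_operator`s on the same number of qubits.
#' @export
qop_mul <- function(a, b) {
  stopifnot(a$n_qubits == b$n_qubits)
  na <- length(a$coef); nb <- length(b$coef)
  ia <- rep(seq_len(na), each = nb); ib <- rep(seq_len(nb), times = na)
  p <- .pmul(a$x1[ia], a$x2[ia], a$z1[ia], a$z2[ia], a$coef[ia],
             b$x1[ib], b$x2[ib], b$z1[ib], b$z2[ib], b$coef[ib])
  qop_collect(new_qop(a$n_qubits, p$x1, p$x2, p$z1, p$z2, p$coef))
}

#' Test whether a qubit operator is Hermitian
#'
#' Each stored Pauli word is Hermitian, so the operator is Hermitian iff
#' all coefficients are real.
#'
#' @param op a `qubit_operator`; @param tol imaginary-part tolerance.
#' @export
is_hermitian_qop <- function(op, tol = 1e-10) {
  length(op$coef) == 0 || max(abs(Im(op$coef))) <= tol
}

#' Number of Pauli strings in an operator
#'
#' Counts the distinct Pauli words, including the identity (constant) term
#' if present. Measuring each string in its own basis ("native Pauli
#' bases") requires this many distinct measurement settings.
#'
#' @param op a `qubit_operator`.
#' @param tol words with coefficient modulus below `tol` are not counted.
#' @export
count_pauli_strings <- function(op, tol = 1e-12) {
  sum(abs(op$coef) > tol)
}

#' Serialize a qubit operator to a line-oriented text form
#'
#' One term per line, `coefficient  word`, e.g. `0.5 X0 Y3`; complex
#' coefficients are written as `re+imi`.
#'
#' @param op a `qubit_operator`; @param path file path.
#' @export
write_qubit_operator <- function(op, path) {
  lines <- vapply(seq_along(op$coef), function(i) {
    cf <- op$coef[i]
    cs <- if (abs(Im(cf)) < 1e-14) sprintf("%.16g", Re(cf))
          else sprintf("%.16g%+.16gi", Re(cf), Im(cf))
    paste(cs, .format_word(op$x1[i], op$x2[i], op$z1[i], op$z2[i], op$n_qubits))
  }, character(1))
  writeLines(c(sprintf("# qubit_operator n_qubits=%d", op$n_qubits), lines), path)
}

#' Read a qubit operator written by [write_qubit_operator()]
#' @param path file path.
#' @export
read_qubit_operator <- function(path) {
  lines <- readLines(path)
  hdr <- regmatches(lines[1], regexec("n_qubits=(\\d+)", lines[1]))[[1]]
  if (length(hdr) < 2) stop("missing qubit_operator header in ", path)
  nq <- as.integer(hdr[2])
  lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  words <- character(length(lines)); coef <- complex(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    coef[i] <- as.complex(parts[1])
    words[i] <- paste(parts[-1], collapse = " ")
  }
  qop(nq, words, coef)
}
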