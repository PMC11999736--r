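RNA_BASES <- c("A", "C", "G", "U")

#' Define a ribozyme secondary-structure constraint
#'
#' A motif of length `Lstr` is described by the positions whose base is
#' conserved, the position pairs that must form a canonical base pair
#' (GC, CG, AU, UA, GU or UG), and break points splitting the motif into
#' modules between which extra bases can be inserted without loss of
#' function. Coordinates are 1-based and inclusive.
#'
#' A stem position with a required base is entered as two conserved sites,
#' not as a pair: the sequence requirement already enforces pairing, so
#' counting it again as a pairing constraint would double-count. Pairs must
#' therefore have both sides variable; a pair touching a conserved position
#' is rejected. Pseudoknotted pairs are treated exactly like nested ones —
#' each is a single independent 3/8 constraint.
#'
#' @param Lstr Motif length in nucleotides.
#' @param conserved Named character vector: names are positions, values are
#'   required bases (`A`, `C`, `G`, `U`; `T` is normalised to `U`). May be
#'   empty.
#' @param pairs Two-column matrix (or list of length-2 vectors) of paired
#'   positions, `i < j` after sorting. May be empty.
#' @param breaks Integer positions after which a module boundary falls
#'   (1 <= break < Lstr). `M = length(breaks) + 1` modules result.
#' @param anchored5 If `TRUE` the first module is fixed at the 5' end of the
#'   randomized region (e.g. when the reaction chemistry acts on the 5'
#'   terminus), which removes one placement degree of freedom.
#' @param name Optional motif name.
#' @return An object of class `structure_constraint` with derived counts
#'   `s` (conserved sites), `b` (pairs) and `M` (modules).
#' @examples
#' toy <- structure_constraint(4, conserved = c(`1` = "G"),
#'                             pairs = rbind(c(2, 4)))
#' toy$s; toy$b
#' @export
structure_constraint <- function(Lstr, conserved = character(), pairs = NULL,
                                 breaks = integer(), anchored5 = FALSE,
                                 name = NULL) {
  if (!is.numeric(Lstr) || length(Lstr) != 1 || Lstr < 1 || Lstr != floor(Lstr)) {
    abort("`Lstr` must be a single positive integer.")
  }
  Lstr <- as.integer(Lstr)

  cons_pos <- integer()
  cons_base <- character()
  if (length(conserved)) {
    if (is.null(names(conserved))) abort("`conserved` must be named by position.")
    cons_pos <- as.integer(names(conserved))
    cons_base <- toupper(as.character(conserved))
    cons_base[cons_base == "T"] <- "U"
    if (anyNA(cons_pos) || any(cons_pos < 1) || any(cons_pos > Lstr)) {
      abort("conserved positions must lie in 1..Lstr.")
    }
    if (anyDuplicated(cons_pos)) abort("duplicate conserved position.")
    if (!all(cons_base %in% RNA_BASES)) {
      abort("conserved bases must be A, C, G or U (T accepted as U).")
    }
    ord <- order(cons_pos)
    cons_pos <- cons_pos[ord]; cons_base <- cons_base[ord]
  }

  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0) ||
      length(pairs) == 0) {
    pairs <- matrix(integer(), ncol = 2)
  } else {
    if (is.list(pairs)) pairs <- do.call(rbind, pairs)
    pairs <- matrix(as.integer(pairs), ncol = 2)
    pairs <- t(apply(pairs, 1, sort))
    if (any(pairs < 1) || any(pairs > Lstr)) abort("pair positions must lie in 1..Lstr.")
    if (any(pairs[, 1] == pairs[, 2])) abort("a position cannot pair with itself.")
    touched <- as.vector(pairs)
    if (anyDuplicated(touched)) abort("a position occurs in two pairs.")
    clash <- intersect(touched, cons_pos)
    if (length(clash)) {
      abort(paste0("position(s) ", paste(clash, collapse = ", "),
                   " are both conserved and paired; enter a conserved stem ",
                   "base as two conserved sites instead of a pair."))
    }
  }

  breaks <- as.integer(breaks)
  if (length(breaks)) {
    if (any(breaks < 1) || any(breaks >= Lstr)) {
      abort("break points must satisfy 1 <= break < Lstr.")
    }
    if (anyDuplicated(breaks)) abort("duplicate break point.")
    breaks <- sort(breaks)
  }

  s <- length(cons_pos); b <- nrow(pairs); M <- length(breaks) + 1L
  if (s + 2L * b > Lstr) abort("constraints exceed motif length (s + 2b > Lstr).")

  structure(
    list(name = name, Lstr = Lstr,
         conserved = setNames(cons_base, cons_pos),
         pairs = pairs, breaks = breaks, anchored5 = isTRUE(anchored5),
         s = s, b = b, M = M),
    class = "structure_constraint"
  )
}

#' @export
print.structure_constraint <- function(x, ...) {
  cat(sprintf("<structure_constraint%s> Lstr = %d, s = %d, b = %d, M = %d%s\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$Lstr, x$s, x$b, x$M,
              if (x$anchored5) ", 5'-anchored" else ""))
  invisible(x)
}

# Module boundaries as a (start, end) tibble, 1-based inclusive.
structure_modules <- function(struct) {
  starts <- c(1L, struct$breaks + 1L)
  ends <- c(struct$breaks, struct$Lstr)
  tibble(module = seq_along(starts), start = starts, end = ends)
}

#' Read or write a structure-constraint file
#'
#' Plain-text, line-oriented directive format:
#' \preformatted{
#' NAME hammerhead-like
#' LENGTH 39
#' CONS 4=C 5=U 6=G
#' PAIR 1:12 2:11
#' BREAK 13 26
#' ANCHOR5 false
#' }
#' `CONS`, `PAIR` and `BREAK` lines may repeat and accumulate; `#` starts a
#' comment; blank lines are ignored. [write_structure()] emits the same
#' dialect deterministically so files round-trip bit-exactly.
#'
#' @param path File path.
#' @return [read_structure()] returns a [structure_constraint()];
#'   [write_structure()] returns `path` invisibly.
#' @export
read_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  name <- NULL; Lstr <- NULL; anchored5 <- FALSE
  cons <- character(); pairs <- list(); breaks <- integer()
  for (ln in lines) {
    parts <- strsplit(ln, "[[:space:]]+")[[1]]
    key <- toupper(parts[1]); args <- parts[-1]
    if (key == "NAME") {
      name <- paste(args, collapse = " ")
    } else if (key == "LENGTH") {
      Lstr <- as.integer(args[1])
    } else if (key == "CONS") {
      for (a in args) {
        kv <- strsplit(a, "=", fixed = TRUE)[[1]]
        if (length(kv) != 2) abort(sprintf("malformed CONS entry '%s'.", a))
        pos <- suppressWarnings(as.integer(kv[1]))
        if (is.na(pos) || pos < 1) {
          abort(sprintf("CONS position '%s' is not a positive 1-based coordinate.", kv[1]))
        }
        cons[as.character(pos)] <- kv[2]
      }
    } else if (key == "PAIR") {
      for (a in args) {
        ij <- suppressWarnings(as.integer(strsplit(a, ":", fixed = TRUE)[[1]]))
        if (length(ij) != 2 || anyNA(ij) || any(ij < 1)) {
          abort(sprintf("malformed PAIR entry '%s' (need i:j, 1-based).", a))
        }
        pairs[[length(pairs) + 1]] <- ij
      }
    } else if (key == "BREAK") {
      bp <- suppressWarnings(as.integer(args))
      if (anyNA(bp) || any(bp < 1)) abort("malformed BREAK line.")
      breaks <- c(breaks, bp)
    } else if (key == "ANCHOR5") {
      anchored5 <- tolower(args[1]) %in% c("true", "yes", "1")
    } else {
      abort(sprintf("unknown directive '%s' in structure file.", key))
    }
  }
  if (is.null(Lstr)) abort("structure file lacks a LENGTH line.")
  structure_constraint(Lstr, conserved = cons, pairs = pairs, breaks = breaks,
                       anchored5 = anchored5, name = name)
}

#' @rdname read_structure
#' @param struct A [structure_constraint()].
#' @export
write_structure <- function(struct, path) {
  stopifnot(inherits(struct, "structure_constraint"))
  out <- character()
  if (!is.null(struct$name)) out <- c(out, paste("NAME", struct$name))
  out <- c(out, paste("LENGTH", struct$Lstr))
  if (struct$s > 0) {
    out <- c(out, paste("CONS", paste0(names(struct$conserved), "=",
                                       struct$conserved, collapse = " ")))
  }
  if (struct$b > 0) {
    out <- c(out, paste("PAIR", paste0(struct$pairs[, 1], ":",
                                       struct$pairs[, 2], collapse = " ")))
  }
  if (length(struct$breaks)) {
    out <- c(out, paste("BREAK", paste(struct$breaks, collapse = " ")))
  }
  out <- c(out, paste("ANCHOR5", if (struct$anchored5) "true" else "false"))
  writeLines(out, path)
  invisible(path)
}

#' Probability that a random sequence matches a structure in one frame
#'
#' With equal base frequencies, a conserved site is matched with probability
#' 1/4 and a variable pair forms one of the six canonical base pairs
#' (GC, CG, AU, UA, GU, UG) with probability 6/16 = 3/8, so the probability
#' of satisfying all constraints in a fixed placement is
#' `q = (1/4)^s * (3/8)^b`.
#'
#' @param s Number of conserved sites (or a [structure_constraint()], from
#'   which `s` and `b` are taken).
#' @param b Number of base-pair constraints.
#' @return Probability `q`.
#' @examples
#' exact_match_probability(13, 8) # ~5.8e-12
#' @export
exact_match_probability <- function(s, b = NULL) {
  if (inherits(s, "structure_constraint")) {
    b <- s$b; s <- s$s
  }
  if (s < 0 || b < 0) abort("`s` and `b` must be nonnegative.")
  0.25^s * 0.375^b
}

#' Number of frames in which a structure fits a randomized region
#'
#' The `Lran - Lstr` bases not belonging to the structure are distributed as
#' nonnegative gaps before, between and after the `M` modules; each
#' distinct gap assignment is one frame. Stars-and-bars gives
#' `W = choose(Lran - Lstr + M, M)`, which reduces to the sliding count
#' `Lran - Lstr + 1` for a single module. If the first module is anchored at
#' the 5' end, the leading gap is forced to zero and
#' `W = choose(Lran - Lstr + M - 1, M - 1)`.
#'
#' @param Lran Length of the randomized region.
#' @param Lstr Structure length (or a [structure_constraint()], from which
#'   `Lstr`, `M` and `anchored5` are taken).
#' @param M Number of modules.
#' @param anchored5 Is the first module fixed at the 5' end?
#' @return Number of frames (a plain double; exact for all realistic sizes).
#' @examples
#' frame_count(80, 39, M = 3)                   # 13244
#' frame_count(80, 39, M = 1)                   # 42
#' frame_count(80, 44, M = 2, anchored5 = TRUE) # 37
#' @export
frame_count <- function(Lran, Lstr, M = 1, anchored5 = FALSE) {
  if (inherits(Lstr, "structure_constraint")) {
    M <- Lstr$M; anchored5 <- Lstr$anchored5; Lstr <- Lstr$Lstr
  }
  if (Lran < Lstr) abort("`Lran` must be at least `Lstr`.")
  if (M < 1) abort("`M` must be at least 1.")
  free <- Lran - Lstr
  if (anchored5) choose(free + M - 1, M - 1) else choose(free + M, M)
}

#' Probability of an exact match in at least one frame
#'
#' Treating the `W` frames as independent, the probability that a random
#' sequence matches the structure in at least one of them is
#' `PW = 1 - (1 - q)^W`, for which `W * q` is an excellent approximation
#' whenever `W * q << 1`. Both are returned; overlapping frames make the
#' independence assumption slightly optimistic, an error that is negligible
#' at the exact-match level.
#'
#' @param q Single-frame match probability.
#' @param W Number of frames, >= 1.
#' @return A tibble with columns `q`, `W`, `PW` (`1 - (1-q)^W`) and `Wq`.
#' @examples
#' multi_frame_exact_probability(exact_match_probability(13, 8),
#'                               frame_count(80, 39, M = 3))
#' @export
multi_frame_exact_probability <- function(q, W) {
  if (any(q < 0) || any(q > 1)) abort("`q` must be a probability.")
  if (any(W < 1)) abort("`W` must be at least 1.")
  tibble(q = q, W = W, PW = -expm1(W * log1p(-q)), Wq = W * q)
}

#' Joint distribution of conserved-site and pair mismatches
#'
#' In a single frame, the number of mismatched conserved sites `m1` is
#' binomial(s, 3/4) and the number of non-canonical pairs `m2` is an
#' independent binomial(b, 5/8):
#' `P(m1, m2) = C(s, m1) (3/4)^m1 (1/4)^(s-m1) C(b, m2) (5/8)^m2 (3/8)^(b-m2)`.
#'
#' @param m1 Number of mismatched conserved sites (vectorised).
#' @param m2 Number of non-canonical pairs (vectorised).
#' @param s,b Constraint counts.
#' @return Probability.
#' @export
mismatch_joint_probability <- function(m1, m2, s, b) {
  if (any(m1 < 0) || any(m1 > s) || any(m2 < 0) || any(m2 > b)) {
    abort("need 0 <= m1 <= s and 0 <= m2 <= b.")
  }
  dbinom(m1, s, 0.75) * dbinom(m2, b, 0.625)
}

new_distance_distribution <- function(m, probability, frames = 1L,
                                      s = NA_integer_, b = NA_integer_,
                                      kind = "theoretical") {
  structure(
    tibble(m = as.integer(m), probability = as.numeric(probability)),
    class = c("distance_distribution", class(tibble())),
    frames = frames, s = s, b = b, kind = kind
  )
}

#' Distribution of the mutational distance in a single frame
#'
#' The mutational distance of a random sequence from a structure, in one
#' fixed frame, is `m = m1 + m2`: the total number of violated constraints.
#' Its distribution is the convolution of the two mismatch binomials, and
#' `P(0) = q` exactly.
#'
#' @param s,b Constraint counts (or a [structure_constraint()] as `s`).
#' @return A `distance_distribution`: a tibble with columns `m` (0..s+b)
#'   and `probability`, carrying attributes `frames = 1`, `s`, `b`.
#' @examples
#' single_frame_distribution(13, 8)
#' @export
single_frame_distribution <- function(s, b = NULL) {
  if (inherits(s, "structure_constraint")) {
    b <- s$b; s <- s$s
  }
  if (s < 0 || b < 0) abort("`s` and `b` must be nonnegative.")
  p1 <- dbinom(0:s, s, 0.75)
  p2 <- dbinom(0:b, b, 0.625)
  p <- rep(0, s + b + 1)
  for (i in 0:s) p[i + (0:b) + 1] <- p[i + (0:b) + 1] + p1[i + 1] * p2
  new_distance_distribution(0:(s + b), p, frames = 1L, s = s, b = b)
}

#' Distribution of the best (minimum) distance over W frames
#'
#' With `g(m) = P(single-frame distance >= m)`, and the `W` frames treated
#' as independent, the minimum distance over all frames has
#' `P_W(m) = g(m)^W - g(m+1)^W`. For `m = 0` this reduces to
#' `1 - (1 - q)^W`. Frames overlap in reality, so independence is an
#' approximation — close for small `m`, the regime of interest.
#'
#' @param single A single-frame `distance_distribution`.
#' @param W Number of frames, >= 1.
#' @return A `distance_distribution` over the same support with attribute
#'   `frames = W`.
#' @export
multi_frame_distribution <- function(single, W) {
  stopifnot(inherits(single, "distance_distribution"))
  if (W < 1) abort("`W` must be at least 1.")
  if (W == 1) return(single)
  p <- single$probability
  # work with the complement h(m) = P(distance < m) = 1 - g(m): for small m
  # it is tiny, and exp(W * log1p(-h)) evaluates g(m)^W at full relative
  # precision where it matters (the rare-match tail, h ~ q)
  h <- pmin(c(0, cumsum(p)[-length(p)]), 1)
  gW <- c(exp(W * log1p(-h)), 0)
  pw <- gW[-length(gW)] - gW[-1]
  new_distance_distribution(single$m, pw, frames = W,
                            s = attr(single, "s"), b = attr(single, "b"))
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("<distance_distribution> %s, frames = %s, s = %s, b = %s\n",
              attr(x, "kind"), attr(x, "frames"), attr(x, "s"), attr(x, "b")))
  NextMethod()
}

#' @describeIn single_frame_distribution Log-probability bar chart of a
#'   distance distribution.
#' @param object A `distance_distribution`.
#' @param ... Unused.
#' @export
autoplot.distance_distribution <- function(object, ...) {
  dat <- dplyr::filter(as_tibble(object), .data$probability > 0)
  ggplot2::ggplot(dat, ggplot2::aes(.data$m, .data$probability)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mutational distance m", y = "probability") +
    ggplot2::theme_minimal()
}
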