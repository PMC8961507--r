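#' Parse an EUNet architecture notation string
#'
#' Parses the compact cascade/branch notation into a validated
#' \linkS4class{ArchitectureSpec}. The grammar is
#' \preformatted{spec  := group ('-' group)*
#' group := uterm ('//' uterm)*
#' uterm := 'U' label? '(' int ('-' int)? ')'}
#' \code{"-"} cascades segments in sequence (horizontal extension, forming
#' W-shaped profiles); \code{"//"} places U-structures in parallel branches
#' (spatial extension). A single integer \code{d} inside the parentheses is
#' the symmetric form \code{(d-d)}. Whitespace and subscript/superscript
#' decorations (\code{_}, \code{^}, \code{\{\}}) are ignored; labels such as
#' \code{U_1} or \code{U^1} are opaque branch identifiers. Canonical labels
#' are assigned when absent.
#'
#' Elevation bookkeeping: the input sits at elevation 0; segment i ends at
#' elevation \code{e_{i-1} - down_i + up_i}. The notation is rejected unless
#' the final elevation is 0 (output layer at the input height) and no
#' intermediate peak rises above the input.
#'
#' @param notation Character scalar, e.g. \code{"U_1(4-4)-U_2(4-4)"} (single
#'   high-peak horizontal form), \code{"U_1(4-3)-U_2(3-4)"} (low peak) or
#'   \code{"U_1(4)//U^1(4)"} (double branch).
#' @return An \linkS4class{ArchitectureSpec}.
#' @examples
#' parseArchitecture("U_1(4-4)-U_2(4-4)")
#' parseArchitecture("U_1(4)//U^1(4)")
#' @seealso [formatArchitecture()], [buildLayerGraph()]
#' @export
parseArchitecture <- function(notation) {
  if (!is.character(notation) || length(notation) != 1L || is.na(notation))
    parseError("notation must be a single character string")
  s <- gsub("[[:space:]{}]", "", notation)
  if (!nzchar(s)) parseError("empty notation")

  pos <- 1L
  n <- nchar(s)
  peek <- function(k = 1L) if (pos + k - 1L <= n) substr(s, pos, pos + k - 1L) else ""
  fail <- function(what) {
    tok <- if (pos <= n) substr(s, pos, min(n, pos + 5L)) else "<end of input>"
    parseError("expected %s at position %d near '%s'", what, pos, tok)
  }

  parseInt <- function() {
    m <- regmatches(substr(s, pos, n), regexpr("^[0-9]+", substr(s, pos, n)))
    if (length(m) == 0L) fail("an integer depth")
    pos <<- pos + nchar(m)
    as.integer(m)
  }

  parseUterm <- function() {
    if (peek() != "U") fail("'U'")
    pos <<- pos + 1L
    # label: everything up to the opening parenthesis
    rest <- substr(s, pos, n)
    lab <- regmatches(rest, regexpr("^[^()]*", rest))
    if (grepl("[-/]", lab)) {
      # a '-' or '/' before '(' means the label ran into an operator
      lab <- regmatches(lab, regexpr("^[^-/]*", lab))
    }
    pos <<- pos + nchar(lab)
    if (peek() != "(") fail("'('")
    pos <<- pos + 1L
    d <- parseInt()
    u <- d
    if (peek() == "-") {
      pos <<- pos + 1L
      u <- parseInt()
    }
    if (peek() != ")") fail("')'")
    pos <<- pos + 1L
    label <- if (nzchar(lab)) paste0("U", lab) else NA_character_
    list(label = label, down = d, up = u)
  }

  parseGroup <- function() {
    terms <- list(parseUterm())
    while (peek(2L) == "//") {
      pos <<- pos + 2L
      terms[[length(terms) + 1L]] <- parseUterm()
    }
    terms
  }

  groups <- list(parseGroup())
  while (peek() == "-") {
    pos <- pos + 1L
    groups[[length(groups) + 1L]] <- parseGroup()
  }
  if (pos <= n) fail("'-', '//' or end of notation")

  # depth validity before building S4 objects, for friendlier diagnostics
  for (g in groups) for (t in g) {
    if (t$down < 1L || t$up < 1L)
      validationError("U-structure depths must be >= 1 (got %d-%d)", t$down, t$up)
    if (abs(t$down - t$up) > 1L)
      validationError("down and up depths may differ by at most 1 (got %d-%d)",
                      t$down, t$up)
  }

  for (i in seq_along(groups)) {
    d <- vapply(groups[[i]], `[[`, numeric(1), "down")
    u <- vapply(groups[[i]], `[[`, numeric(1), "up")
    if (length(unique(d)) > 1L || length(unique(u)) > 1L)
      validationError(
        "segment %d: all branches in a parallel group must share the same (down-up) depths",
        i)
  }

  segments <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    branches <- vector("list", length(groups[[i]]))
    for (j in seq_along(groups[[i]])) {
      t <- groups[[i]][[j]]
      lab <- if (is.na(t$label)) canonicalBranchLabel(i, j) else t$label
      branches[[j]] <- new("UStructureSpec", label = lab,
                           down = as.integer(t$down), up = as.integer(t$up))
    }
    grp <- new("BranchGroup", branches = branches)
    v <- validObject(grp, test = TRUE)
    if (!isTRUE(v)) validationError("segment %d: %s", i, v)
    segments[[i]] <- grp
  }

  elev <- integer(length(segments))
  e <- 0L
  for (i in seq_along(segments)) {
    b <- segments[[i]]@branches[[1L]]
    e <- e - b@down + b@up
    if (e > 0L)
      validationError("peak after segment %d rises above the input height", i)
    elev[i] <- e
  }
  if (e != 0L)
    validationError("output not at input height (final elevation %d)", e)

  new("ArchitectureSpec", segments = segments, peakElevations = elev)
}

# canonical labels mirror the field's convention: branch 1 of segment s is
# U_s; branch j > 1 is U^ with the segment digit repeated (U^1, U^11, ...)
canonicalBranchLabel <- function(segment, branch) {
  if (branch == 1L) paste0("U_", segment)
  else paste0("U^", strrep(as.character(segment), branch - 1L))
}

#' Format an architecture back to its canonical notation
#'
#' The canonical form round-trips: \code{parseArchitecture(formatArchitecture(s))}
#' equals \code{s}. Pure cascades print symmetric terms in pair form
#' (\code{"U_1(4-4)"}); architectures containing a parallel group print
#' symmetric terms in the single-number form used for branched structures
#' (\code{"U_1(4)//U^1(4)"}). Asymmetric terms always print as pairs.
#'
#' @param spec An \linkS4class{ArchitectureSpec}.
#' @return Character scalar.
#' @export
formatArchitecture <- function(spec) {
  if (!is(spec, "ArchitectureSpec"))
    argumentError("spec must be an ArchitectureSpec")
  validObject(spec)
  branched <- any(vapply(spec@segments, function(g) length(g@branches) > 1L,
                         logical(1)))
  fmtU <- function(u) {
    depths <- if (u@down == u@up && branched) sprintf("(%d)", u@down)
              else sprintf("(%d-%d)", u@down, u@up)
    paste0(u@label, depths)
  }
  paste(vapply(spec@segments, function(g)
    paste(vapply(g@branches, fmtU, character(1)), collapse = "//"),
    character(1)), collapse = "-")
}

#' @describeIn parseArchitecture Number of parallel branches per segment.
#' @param spec An \linkS4class{ArchitectureSpec}.
#' @export
branchCounts <- function(spec) {
  vapply(spec@segments, function(g) length(g@branches), integer(1))
}

#' @describeIn parseArchitecture Deepest descent (in pooling levels) reached
#'   below the input, i.e. the number of resolution halvings the input must
#'   support.
#' @export
maxDescent <- function(spec) {
  e <- 0L
  deepest <- 0L
  for (g in spec@segments) {
    b <- g@branches[[1L]]
    deepest <- max(deepest, (b@down - 1L) - e)
    e <- e - b@down + b@up
  }
  deepest
}

setMethod("show", "UStructureSpec", function(object) {
  cat(sprintf("%s(%d-%d)\n", object@label, object@down, object@up))
})

setMethod("show", "ArchitectureSpec", function(object) {
  nb <- branchCounts(object)
  cat("ArchitectureSpec:", formatArchitecture(object), "\n")
  cat(sprintf("  %d segment(s); branches per segment: %s\n",
              length(object@segments), paste(nb, collapse = ", ")))
  cat("  peak elevations:", paste(object@peakElevations, collapse = ", "), "\n")
})
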