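#' Compile a PROSITE-dialect pattern
#'
#' Grammar: elements separated by `-`. An element is `[ABC]` (set), `{ABC}`
#' (complement of the set over the 20 standard residues), `x` (any standard
#' residue) or a single residue letter, optionally followed by a repeat
#' count `(m)` or range `(m,n)`. Example:
#' `"[GASTC](2)-x(2,3)-[GASTC](1,2)"`.
#'
#' @param text Pattern string.
#' @param id Optional pattern identifier (defaults to the pattern text).
#' @return A `compiled_pattern`: list with `elements` (each a list with
#'   `set`, `min`, `max`, `role`), `flank_rule = "none"` and `source`.
#' @examples
#' p <- compile_pattern("[GASTC](2)-x(2,3)-[GASTC](1,2)")
#' length(p$elements)
#' @export
compile_pattern <- function(text, id = text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    stop("pattern text must be a non-empty string")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  elements <- list()
  parse_err <- function(msg, pos) {
    stop("pattern parse error at position ", pos, ": ", msg)
  }
  while (i <= n) {
    start <- i
    ch <- chars[i]
    if (ch == "[" || ch == "{") {
      close <- if (ch == "[") "]" else "}"
      j <- i + 1L
      set <- character()
      while (j <= n && chars[j] != close) {
        if (!chars[j] %in% AA_STANDARD) {
          parse_err(paste0("unknown residue letter '", chars[j], "'"), j)
        }
        set <- c(set, chars[j])
        j <- j + 1L
      }
      if (j > n) parse_err(paste0("unbalanced '", ch, "'"), start)
      if (length(set) == 0L) parse_err("empty residue set", start)
      if (ch == "{") set <- setdiff(AA_STANDARD, set)
      i <- j + 1L
    } else if (ch == "x") {
      set <- AA_STANDARD
      i <- i + 1L
    } else if (ch %in% AA_STANDARD) {
      set <- ch
      i <- i + 1L
    } else if (ch == "]" || ch == "}") {
      parse_err(paste0("unbalanced '", ch, "'"), i)
    } else {
      parse_err(paste0("unexpected character '", ch, "'"), i)
    }
    mn <- 1L
    mx <- 1L
    if (i <= n && chars[i] == "(") {
      j <- i + 1L
      while (j <= n && chars[j] != ")") j <- j + 1L
      if (j > n) parse_err("unbalanced '('", i)
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
      nums <- suppressWarnings(as.integer(parts))
      if (length(nums) < 1L || length(nums) > 2L || anyNA(nums)) {
        parse_err(paste0("bad repeat specifier '(", inner, ")'"), i)
      }
      mn <- nums[1]
      mx <- if (length(nums) == 2L) nums[2] else nums[1]
      if (mn < 1L || mn > mx) {
        parse_err(paste0("repeat range (", mn, ",", mx, ") requires 1 <= m <= n"), i)
      }
      i <- j + 1L
    }
    elements[[length(elements) + 1L]] <-
      list(set = unique(set), min = mn, max = mx, role = NA_character_)
    if (i <= n) {
      if (chars[i] != "-") parse_err("expected '-' between elements", i)
      i <- i + 1L
      if (i > n) parse_err("trailing '-'", i - 1L)
    }
  }
  if (length(elements) == 0L) stop("pattern has no elements")
  structure(list(elements = elements, flank_rule = "none",
                 source = text, id = id),
            class = "compiled_pattern")
}

#' @export
print.compiled_pattern <- function(x, ...) {
  cat("Compiled pattern <", x$id, ">: ", length(x$elements),
      " element(s)\n", sep = "")
  for (el in x$elements) {
    cat("  [", paste(el$set, collapse = ""), "] x ", el$min,
        if (el$max > el$min) paste0("-", el$max) else "",
        if (!is.na(el$role)) paste0("  (", el$role, ")") else "",
        "\n", sep = "")
  }
  invisible(x)
}

.ccm_variant <- function(scheme, sep_len, p2_len, flank_side) {
  core <- list(
    list(set = scheme$small, min = 2L, max = 2L, role = "patch1"),
    list(set = scheme$bulky, min = sep_len, max = sep_len, role = "separator"),
    list(set = scheme$small, min = p2_len, max = p2_len, role = "patch2")
  )
  fl <- list(set = scheme$flank, min = 1L, max = 1L, role = "flank")
  elements <- switch(flank_side,
    left = c(list(fl), core),
    right = c(core, list(fl)),
    both = c(list(fl), core, list(fl))
  )
  structure(list(elements = elements, flank_rule = flank_side,
                 source = NA_character_,
                 id = sprintf("ccm/s%dp%d/%s", sep_len, p2_len, flank_side),
                 sep_len = sep_len, p2_len = p2_len, flank_side = flank_side),
            class = "compiled_pattern")
}

#' Build the conformational consensus motif pattern family
#'
#' The motif consists of two patches of small residues — the first of two,
#' the second of one or two residues — separated by two or three bulky
#' residues and flanked on one or both sides by a large charged, large
#' polar or aromatic residue immediately adjacent to a patch. Expanding
#' the alternatives (separator length 2 or 3, second patch length 1 or 2,
#' flank on the left, right or both sides) gives 12 concrete variants.
#'
#' @param scheme A [residue_scheme()].
#' @param flank_rule Which flank placements count as a match:
#'   `"either_required"` (default; left-only, right-only and both-sided
#'   variants all match), `"left_required"`, `"right_required"`,
#'   `"both_required"`.
#' @return A `ccm_family` object: list with `scheme`, `flank_rule` and
#'   `variants` (12 `compiled_pattern`s).
#' @examples
#' fam <- ccm_pattern_family()
#' length(fam$variants)
#' @export
ccm_pattern_family <- function(scheme = residue_scheme(),
                               flank_rule = c("either_required",
                                              "left_required",
                                              "right_required",
                                              "both_required")) {
  stopifnot(inherits(scheme, "residue_scheme"))
  flank_rule <- match.arg(flank_rule)
  variants <- list()
  for (sep_len in 2:3) {
    for (p2_len in 1:2) {
      for (side in c("left", "right", "both")) {
        variants[[length(variants) + 1L]] <-
          .ccm_variant(scheme, sep_len, p2_len, side)
      }
    }
  }
  structure(list(scheme = scheme, flank_rule = flank_rule,
                 variants = variants),
            class = "ccm_family")
}

#' @export
print.ccm_family <- function(x, ...) {
  cat("Conformational consensus motif family (", length(x$variants),
      " variants, flank rule ", x$flank_rule, ")\n", sep = "")
  print(x$scheme)
  invisible(x)
}
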