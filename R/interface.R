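#' BDT geometry: locations, paths and the task interface
#'
#' The task environment is a binary decision tree (BDT) of `depth` levels.
#' A *location* is one clickable slot of the tree and is encoded as the
#' bit-string of the choices that reach it, including its own side: the two
#' level-1 slots are `"0"` (left) and `"1"` (right), the level-2 slot reached
#' by left-then-right is `"01"`, and so on. A *path* is the bit-string of a
#' full root-to-leaf sequence (`depth` bits), so at depth 4 there are 16
#' paths and 2 + 4 + 8 + 16 = 30 location slots.
#'
#' @name bdt-geometry
NULL

#' @describeIn bdt-geometry Level of a location (number of bits).
#' @param loc,path Location / path bit-strings.
#' @export
loc_level <- function(loc) nchar(loc)

#' @describeIn bdt-geometry Side of a location: `0` = left, `1` = right.
#' @export
loc_side <- function(loc) substr(loc, nchar(loc), nchar(loc))

#' @describeIn bdt-geometry Prefix (choices made before reaching the slot).
#' @export
loc_prefix <- function(loc) substr(loc, 1L, nchar(loc) - 1L)

#' @describeIn bdt-geometry The sibling slot on the same screen.
#' @export
loc_neighbor <- function(loc) {
  n <- nchar(loc)
  last <- substr(loc, n, n)
  paste0(substr(loc, 1L, n - 1L), if (last == "0") "1" else "0")
}

#' @describeIn bdt-geometry The location one level up that leads to `loc`
#'   (`NA` for level-1 slots).
#' @export
loc_parent <- function(loc) {
  if (nchar(loc) <= 1L) NA_character_ else substr(loc, 1L, nchar(loc) - 1L)
}

#' @describeIn bdt-geometry `loc` together with every slot below it.
#' @param depth Tree depth.
#' @export
loc_subtree <- function(loc, depth) {
  locs <- all_locations(depth)
  locs[startsWith(locs, loc)]
}

#' @describeIn bdt-geometry All location slots of a depth-`depth` tree.
#' @export
all_locations <- function(depth) {
  unlist(lapply(seq_len(depth), function(l) {
    apply(expand.grid(rep(list(c("0", "1")), l))[, rev(seq_len(l)), drop = FALSE],
          1L, paste0, collapse = "")
  }), use.names = FALSE)
}

#' @describeIn bdt-geometry All `2^depth` root-to-leaf paths.
#' @export
all_paths <- function(depth) {
  locs <- all_locations(depth)
  sort(locs[nchar(locs) == depth])
}

#' @describeIn bdt-geometry The `depth` locations visited by a path, level
#'   by level.
#' @export
path_locations <- function(path) {
  vapply(seq_len(nchar(path)), function(l) substr(path, 1L, l), character(1))
}

#' @describeIn bdt-geometry Whether a location is a leaf (deepest level).
#' @export
loc_is_leaf <- function(loc, depth) nchar(loc) == depth

#' Default concept vocabulary
#'
#' Supplies two concept words per choice context: 2 verbs at level 1, two
#' nouns per level-2/3 context, and the shared adjective pair
#' `small`/`large` at the last level (the last-level screen is identical in
#' every branch). At depth 4 this is 2 + 4 + 8 + 2 = 16 words.
#'
#' @param depth Tree depth (>= 2).
#' @return A list with one character vector per level.
#' @export
default_vocab <- function(depth = 4L) {
  pool <- list(
    c("feed", "wash"),
    c("cat", "dog", "bird", "horse"),
    c("fish", "bone", "seed", "apple", "brush", "soap", "towel", "sponge")
  )
  vocab <- vector("list", depth)
  for (l in seq_len(depth - 1L)) {
    need <- 2L^l
    words <- if (l <= length(pool)) pool[[l]] else paste0("w", l, "_", seq_len(need))
    if (length(words) < need) words <- paste0("w", l, "_", seq_len(need))
    vocab[[l]] <- words[seq_len(need)]
  }
  vocab[[depth]] <- c("small", "large")
  vocab
}

icon_context <- function(icon) {
  # icons at levels < depth are identified with their slot; the two shared
  # last-level icons are "*0"/"*1" and live in the single leaf context "*".
  if (startsWith(icon, "*")) "*" else loc_prefix(icon)
}

icon_complement <- function(icon) {
  if (startsWith(icon, "*")) {
    if (icon == "*0") "*1" else "*0"
  } else {
    loc_neighbor(icon)
  }
}

#' Build a BDT task interface
#'
#' Constructs the concept-to-icon mapping of a depth-`depth` BDT with a
#' shared last-level screen: at depth 4 there are 8 choice contexts
#' (1 + 2 + 4 + 1) and 16 distinct icons (2 + 4 + 8 + 2). Within each
#' context the two concept words allotted to it are assigned to the left and
#' right icon by a seeded random permutation, so identical seeds give
#' identical interfaces.
#'
#' @param depth Tree depth (default 4).
#' @param vocab Concept vocabulary, as produced by [default_vocab()]:
#'   a list with `2^level` words for levels below the last and exactly 2
#'   words for the shared last level.
#' @param seed Integer seed for the concept-icon assignment.
#' @return An object of class `bdt_interface` with elements `depth`,
#'   `locations`, `contexts`, `icon_of` (location -> icon id), `concept_of`
#'   (icon id -> concept word), `seed` and `vocab`.
#' @export
#' @examples
#' iface <- build_interface(seed = 1)
#' length(unique(iface$icon_of))   # 16 icons
build_interface <- function(depth = 4L, vocab = default_vocab(depth), seed = 1L) {
  if (!is_count(depth) || depth < 2L) stopf("`depth` must be an integer >= 2")
  if (length(vocab) != depth) {
    stopf("vocabulary must provide one word list per level (%d levels)", depth)
  }
  for (l in seq_len(depth - 1L)) {
    if (length(vocab[[l]]) != 2L^l) {
      stopf("configuration error at level %d: need %d concepts, got %d",
            l, 2L^l, length(vocab[[l]]))
    }
  }
  if (length(vocab[[depth]]) != 2L) {
    stopf("configuration error at level %d: the shared last level needs exactly 2 concepts",
          depth)
  }
  if (anyDuplicated(unlist(vocab))) stopf("concept words must be distinct")

  locations <- all_locations(depth)
  # icon identity: one icon per slot at levels < depth; the two last-level
  # icons are shared across every branch.
  icon_of <- vapply(locations, function(p) {
    if (loc_is_leaf(p, depth)) paste0("*", loc_side(p)) else p
  }, character(1))
  icons <- unique(unname(icon_of))

  contexts <- c(
    unlist(lapply(seq_len(depth - 1L) - 1L, function(l) {
      if (l == 0L) "" else {
        apply(expand.grid(rep(list(c("0", "1")), l))[, rev(seq_len(l)), drop = FALSE],
              1L, paste0, collapse = "")
      }
    }), use.names = FALSE),
    "*"
  )

  concept_of <- with_seed(seed, {
    out <- character(0)
    for (l in seq_len(depth - 1L)) {
      prefixes <- if (l == 1L) "" else sort(unique(loc_prefix(
        locations[nchar(locations) == l]
      )))
      words <- vocab[[l]]
      for (k in seq_along(prefixes)) {
        pair <- words[c(2L * k - 1L, 2L * k)]
        pair <- pair[sample.int(2L)]
        names(pair) <- paste0(prefixes[k], c("0", "1"))
        out <- c(out, pair)
      }
    }
    pair <- vocab[[depth]][sample.int(2L)]
    names(pair) <- c("*0", "*1")
    c(out, pair)
  })
  concept_of <- concept_of[icons]

  structure(
    list(depth = depth, locations = locations, contexts = contexts,
         icon_of = icon_of, concept_of = concept_of,
         seed = as.integer(seed), vocab = vocab),
    class = "bdt_interface"
  )
}

#' @export
print.bdt_interface <- function(x, ...) {
  cat(sprintf("<bdt_interface> depth %d: %d locations, %d contexts, %d icons (seed %d)\n",
              x$depth, length(x$locations), length(x$contexts),
              length(x$concept_of), x$seed))
  invisible(x)
}

#' Enumerate all task instances of an interface
#'
#' A task instance pairs a tree-consistent instruction (one concept per
#' level, each available in the context reached by the previous choices)
#' with its unique target path. A depth-`d` interface has exactly `2^d`
#' instances.
#'
#' @param interface A [build_interface()] object.
#' @return A list of task instances, each a list with `index`,
#'   `instruction` (character vector of concepts) and `target` (path
#'   bit-string).
#' @export
enumerate_instructions <- function(interface) {
  stopifnot(inherits(interface, "bdt_interface"))
  paths <- all_paths(interface$depth)
  lapply(seq_along(paths), function(i) {
    locs <- path_locations(paths[i])
    instr <- unname(interface$concept_of[interface$icon_of[locs]])
    list(index = i, instruction = instr, target = paths[i])
  })
}

#' Resolve an instruction to its target path
#'
#' Walks the tree level by level, at each context picking the side whose
#' icon bears the instructed concept.
#'
#' @param interface A [build_interface()] object.
#' @param instruction Character vector of `depth` concept words.
#' @return The target path bit-string.
#' @export
target_path <- function(interface, instruction) {
  stopifnot(inherits(interface, "bdt_interface"))
  if (length(instruction) != interface$depth) {
    stopf("instruction must have %d concepts, got %d",
          interface$depth, length(instruction))
  }
  prefix <- ""
  for (l in seq_len(interface$depth)) {
    sides <- paste0(prefix, c("0", "1"))
    words <- unname(interface$concept_of[interface$icon_of[sides]])
    hit <- which(words == instruction[[l]])
    if (length(hit) != 1L) {
      stopf("invalid instruction at level %d: concept '%s' is not available in this context",
            l, instruction[[l]])
    }
    prefix <- sides[hit]
  }
  prefix
}

#' Compare a chosen path against the target
#'
#' Feedback is positive iff the chosen path equals the target at every
#' level; a negative result carries no information about which level was
#' wrong.
#'
#' @param chosen,target Path bit-strings of equal depth.
#' @return `"pos"` or `"neg"`.
#' @export
evaluate_feedback <- function(chosen, target) {
  if (nchar(chosen) != nchar(target)) {
    stopf("depth mismatch: chosen path has %d levels, target %d",
          nchar(chosen), nchar(target))
  }
  if (identical(chosen, target)) "pos" else "neg"
}
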