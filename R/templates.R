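# Template geometry. Coordinates are 1-based, inclusive, on the RNA template;
# the RT moves 3'->5' on the template, i.e. from high coordinates toward
# coordinate 1. The primer occupies [primer_anchor - primer_len + 1,
# primer_anchor]; the first incorporated nucleotide sits one position below the
# primer window, and a full-length (run-off) product has length primer_anchor.

#' Describe a structural obstacle on the template
#'
#' An obstacle models a stable RNA substructure (such as a GC-rich stem-loop)
#' that can terminate elongation. `stall_coord` is the template coordinate of
#' the last nucleotide a blocked molecule incorporates -- the base of the
#' stem for a stem-loop roadblock. `p_stop` is the per-encounter probability
#' that a molecule terminates there; molecules that pass are unaffected.
#'
#' @param stall_coord 1-based template coordinate of the stall position.
#' @param p_stop Per-encounter termination probability in `[0, 1]`.
#' @param label Short name used in tables and obstacle overrides.
#' @return An object of class `rt_obstacle`.
#' @export
#' @examples
#' obstacle(1550, p_stop = 0.86, label = "GCSL")
obstacle <- function(stall_coord, p_stop, label = "obstacle") {
  stall_coord <- as.integer(stall_coord)
  stopifnot(length(stall_coord) == 1L, stall_coord >= 1L)
  if (!is.numeric(p_stop) || length(p_stop) != 1L || p_stop < 0 || p_stop > 1) {
    stop("`p_stop` must be a single probability in [0, 1]", call. = FALSE)
  }
  structure(
    list(stall_coord = stall_coord, p_stop = as.numeric(p_stop),
         label = as.character(label)),
    class = "rt_obstacle"
  )
}

#' Construct a template specification
#'
#' Low-level constructor; most users want [build_wt_template()] or
#' [gcsl_template()]. Validates the primer window and all obstacle
#' coordinates against the geometry invariants.
#'
#' @param name Template name (also used as the SAM reference name).
#' @param length Template length in nucleotides.
#' @param primer_anchor 1-based coordinate paired with the primer's 5' end.
#'   Because the labeled primer is included in the product, the full-length
#'   product length equals `primer_anchor`.
#' @param primer_len Primer length in nucleotides (default 20).
#' @param obstacles List of [obstacle()] entries.
#' @param sequence Optional template sequence (DNA-sense character string of
#'   length `length`); required only for read emission.
#' @return An object of class `rt_template`.
#' @export
template_spec <- function(name, length, primer_anchor, primer_len = 20L,
                          obstacles = list(), sequence = NULL) {
  length <- as.integer(length)
  primer_anchor <- as.integer(primer_anchor)
  primer_len <- as.integer(primer_len)
  stopifnot(length >= 1L, primer_len >= 1L)
  if (primer_anchor < 1L || primer_anchor > length) {
    stop("`primer_anchor` must lie within [1, length]", call. = FALSE)
  }
  if (primer_anchor - primer_len + 1L < 1L) {
    stop("primer window extends past the template 3' end", call. = FALSE)
  }
  if (inherits(obstacles, "rt_obstacle")) obstacles <- list(obstacles)
  for (ob in obstacles) {
    if (!inherits(ob, "rt_obstacle")) {
      stop("`obstacles` must be a list of obstacle() entries", call. = FALSE)
    }
    if (ob$stall_coord <= 1L || ob$stall_coord >= primer_anchor - primer_len) {
      stop("obstacle stall coordinate must lie strictly between 1 and ",
           "the primer window (downstream of the primer in the direction ",
           "of synthesis)", call. = FALSE)
    }
  }
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != length) {
      stop("`sequence` must have exactly `length` characters", call. = FALSE)
    }
  }
  structure(
    list(name = as.character(name), length = length,
         primer_anchor = primer_anchor, primer_len = primer_len,
         obstacles = obstacles, sequence = sequence),
    class = "rt_template"
  )
}

#' @export
print.rt_template <- function(x, ...) {
  cat("<rt_template> ", x$name, "\n", sep = "")
  cat("  length        : ", x$length, " nt\n", sep = "")
  cat("  primer window : [", primer_window_start(x), ", ", x$primer_anchor,
      "] (", x$primer_len, " nt)\n", sep = "")
  cat("  full-length   : ", full_length(x), " nt\n", sep = "")
  if (length(x$obstacles)) {
    for (ob in x$obstacles) {
      cat("  obstacle      : ", ob$label, " at ", ob$stall_coord,
          " (p_stop = ", ob$p_stop, ")\n", sep = "")
    }
  } else {
    cat("  obstacle      : none\n")
  }
  cat("  sequence      : ", if (is.null(x$sequence)) "absent" else "present",
      "\n", sep = "")
  invisible(x)
}

#' Template geometry accessors
#'
#' `full_length()` is the run-off product length (equal to the primer anchor,
#' since the labeled primer is part of the product). `primer_window_start()`
#' is the 3'-most template coordinate occupied by the primer, and
#' `max_extension()` the number of nucleotides a molecule can incorporate
#' before running off the template 5' end.
#'
#' @param spec An `rt_template`.
#' @return A single integer.
#' @export
full_length <- function(spec) {
  stopifnot(inherits(spec, "rt_template"))
  spec$primer_anchor
}

#' @rdname full_length
#' @export
primer_window_start <- function(spec) {
  stopifnot(inherits(spec, "rt_template"))
  spec$primer_anchor - spec$primer_len + 1L
}

#' @rdname full_length
#' @export
max_extension <- function(spec) {
  primer_window_start(spec) - 1L
}

#' Build an obstacle-free wild-type template
#'
#' Defaults describe a 2148-nt HOTAIR-like lncRNA template with a 20-nt
#' primer anchored so that the full-length cDNA is 1883 nt.
#'
#' @inheritParams template_spec
#' @return An `rt_template` with no obstacles.
#' @export
#' @examples
#' wt <- build_wt_template()
#' full_length(wt) # 1883
build_wt_template <- function(length = 2148L, primer_anchor = 1883L,
                              primer_len = 20L, name = "HOTAIR_like") {
  template_spec(name = name, length = length, primer_anchor = primer_anchor,
                primer_len = primer_len)
}

#' cDNA product length for a molecule whose last incorporated nucleotide is
#' `p_last`
#'
#' The product includes the primer (the label sits on the primer's 5' end),
#' so `product_length(spec, p_last) = primer_anchor - p_last + 1`. A molecule
#' that never extends has `p_last = primer_window_start(spec)` and product
#' length `primer_len`; a run-off molecule has `p_last = 1` and product
#' length `full_length(spec)`.
#'
#' @param spec An `rt_template`.
#' @param p_last Integer vector of template coordinates of the last
#'   incorporated nucleotide (or the primer window start for unextended
#'   molecules).
#' @return Integer vector of product lengths in nucleotides.
#' @export
#' @examples
#' wt <- build_wt_template()
#' product_length(wt, 1)    # 1883 (full length)
#' product_length(wt, 1863) # 21 (one nucleotide incorporated)
product_length <- function(spec, p_last) {
  stopifnot(inherits(spec, "rt_template"))
  p_last <- as.integer(p_last)
  pw <- primer_window_start(spec)
  if (any(p_last < 1L)) {
    stop("`p_last` lies beyond the template 5' end", call. = FALSE)
  }
  if (any(p_last > pw)) {
    stop("`p_last` lies inside or beyond the primer window", call. = FALSE)
  }
  spec$primer_anchor - p_last + 1L
}

#' Insert a structural obstacle into a template
#'
#' Splices an `insert_len`-nt region immediately after template coordinate
#' `insert_after`, shifting every downstream coordinate (including the primer
#' window) by `insert_len`, and registers an obstacle at `stall_coord` given
#' in the *new* coordinate frame. With `insert_len = 0` and no stall
#' coordinate the spec is returned unchanged (identity bookkeeping).
#'
#' If the spec carries a sequence, a GC-rich insert sequence is generated for
#' the spliced region (drawing from the current RNG state); the insert's
#' internal layout is metadata only and has no kinetic effect.
#'
#' @param spec An `rt_template`.
#' @param insert_len Length of the inserted region (>= 0).
#' @param insert_after Coordinate after which the insertion occurs; must lie
#'   upstream of the primer window.
#' @param stall_coord Stall coordinate of the new obstacle in the
#'   post-insertion frame; must fall inside the inserted region. `NULL`
#'   records no obstacle.
#' @param p_stop Per-encounter termination probability of the new obstacle.
#' @param label Obstacle label.
#' @return A new `rt_template`.
#' @export
#' @examples
#' wt <- build_wt_template()
#' gcsl <- insert_obstacle(wt, 44, 1512, 1550, 0.86, label = "GCSL")
#' product_length(gcsl, 1550) # 378
insert_obstacle <- function(spec, insert_len, insert_after,
                            stall_coord = NULL, p_stop = NULL,
                            label = "obstacle") {
  stopifnot(inherits(spec, "rt_template"))
  insert_len <- as.integer(insert_len)
  insert_after <- as.integer(insert_after)
  stopifnot(insert_len >= 0L, insert_after >= 1L)
  if (insert_after >= primer_window_start(spec)) {
    stop("insertion point lies inside or beyond the primer window",
         call. = FALSE)
  }
  if (insert_len == 0L && is.null(stall_coord)) {
    return(spec)
  }
  new_len <- spec$length + insert_len
  new_anchor <- spec$primer_anchor + insert_len
  shifted <- lapply(spec$obstacles, function(ob) {
    if (ob$stall_coord > insert_after) {
      ob$stall_coord <- ob$stall_coord + insert_len
    }
    ob
  })
  if (!is.null(stall_coord)) {
    stall_coord <- as.integer(stall_coord)
    if (stall_coord < insert_after + 1L ||
        stall_coord > insert_after + insert_len) {
      stop("`stall_coord` must fall inside the inserted region [",
           insert_after + 1L, ", ", insert_after + insert_len, "]",
           call. = FALSE)
    }
    shifted <- c(shifted, list(obstacle(stall_coord, p_stop, label)))
  }
  new_seq <- spec$sequence
  if (!is.null(new_seq) && insert_len > 0L) {
    ins <- paste(sample(c("G", "C", "A", "T"), insert_len, replace = TRUE,
                        prob = c(0.4, 0.4, 0.1, 0.1)), collapse = "")
    new_seq <- paste0(substr(new_seq, 1L, insert_after), ins,
                      substr(new_seq, insert_after + 1L, spec$length))
  }
  template_spec(name = spec$name, length = new_len,
                primer_anchor = new_anchor, primer_len = spec$primer_len,
                obstacles = shifted, sequence = new_seq)
}

#' Reverse an insertion (coordinate bookkeeping inverse)
#'
#' Removes the region `(insert_after, insert_after + insert_len]`, shifting
#' downstream coordinates back and dropping any obstacle registered inside
#' the removed region. `remove_insert(insert_obstacle(spec, n, a, ...), n, a)`
#' restores the original geometry.
#'
#' @inheritParams insert_obstacle
#' @return A new `rt_template`.
#' @export
remove_insert <- function(spec, insert_len, insert_after) {
  stopifnot(inherits(spec, "rt_template"))
  insert_len <- as.integer(insert_len)
  insert_after <- as.integer(insert_after)
  if (insert_len == 0L) return(spec)
  kept <- list()
  for (ob in spec$obstacles) {
    if (ob$stall_coord > insert_after + insert_len) {
      ob$stall_coord <- ob$stall_coord - insert_len
      kept <- c(kept, list(ob))
    } else if (ob$stall_coord <= insert_after) {
      kept <- c(kept, list(ob))
    } # obstacles inside the removed region are dropped
  }
  new_seq <- spec$sequence
  if (!is.null(new_seq)) {
    new_seq <- paste0(substr(new_seq, 1L, insert_after),
                      substr(new_seq, insert_after + insert_len + 1L,
                             spec$length))
  }
  template_spec(name = spec$name, length = spec$length - insert_len,
                primer_anchor = spec$primer_anchor - insert_len,
                primer_len = spec$primer_len, obstacles = kept,
                sequence = new_seq)
}

#' GC stem-loop challenge template
#'
#' Convenience wrapper reproducing the GCSL construct geometry: a 44-nt
#' GC-rich stem-loop spliced into the wild-type template between positions
#' 1512 and 1513, with the stall at nucleotide 1550, so that a blocked
#' molecule yields a 378-nt truncated product.
#'
#' @param p_stop Per-encounter stop probability at the stem-loop base
#'   (0.08, 0.26 and 0.86 are the enzyme-dependent values for the MRT-,
#'   TGIRT- and SSIV-class profiles respectively).
#' @param wt Wild-type template to insert into.
#' @return An `rt_template` of length 2192 with primer anchor 1927.
#' @export
#' @examples
#' gcsl <- gcsl_template(0.86)
#' product_length(gcsl, 1550) # 378
gcsl_template <- function(p_stop = 0.86, wt = build_wt_template()) {
  insert_obstacle(wt, insert_len = 44L, insert_after = 1512L,
                  stall_coord = 1550L, p_stop = p_stop, label = "GCSL")
}

#' Attach a pseudo-random sequence to a template
#'
#' Generates a DNA-sense template sequence with a linear GC-content gradient
#' from the 5' end (`gc_start`) to the 3' end (`gc_end`), echoing the
#' gradual 5'-to-3' GC decrease of long structured lncRNA templates. The
#' gradient has no kinetic effect (the stepping model is sequence-agnostic);
#' it only provides realistic read content. Draws from the current RNG state.
#'
#' @param spec An `rt_template`.
#' @param gc_start,gc_end GC fraction at the template 5' and 3' ends.
#' @return The spec with `sequence` populated.
#' @export
add_template_sequence <- function(spec, gc_start = 0.6, gc_end = 0.4) {
  stopifnot(inherits(spec, "rt_template"))
  gc <- seq(gc_start, gc_end, length.out = spec$length)
  is_gc <- stats::runif(spec$length) < gc
  base <- ifelse(is_gc,
                 sample(c("G", "C"), spec$length, replace = TRUE),
                 sample(c("A", "T"), spec$length, replace = TRUE))
  spec$sequence <- paste(base, collapse = "")
  spec
}
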