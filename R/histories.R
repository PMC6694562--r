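#' Evolutionary histories of a genomic region
#'
#' A history is an ordered sequence of loss/gain events taking a region from
#' the germline heterozygous state (1,1) to its observed allele-specific copy
#' state. Each history implies a set of SNV multiplicity classes: SNVs that
#' arise in a given inter-event interval on a given set of copies end up on a
#' characteristic number of final copies (the multiplicity m), which is what
#' makes histories distinguishable from MAF profiles and timeable on the
#' mutational clock.
#'
#' Internally a history carries:
#' * `events`: data frame with `kind` ("loss", "gain", "cn_loh"),
#'   `copies_added` (net change), one row per event, in time order; event
#'   times are symbolic (event 1 happens at t1 < t2 < ...) until instantiated
#'   by the simulator or a timing fit.
#' * `classes`: data frame with one row per (interval, multiplicity):
#'   `interval` (0 = before the first event, k = after event k),
#'   `m` (final multiplicity of SNVs arising then and there), and
#'   `copies` (number of copies on which such SNVs accrue per unit time).
#'
#' @name evolution_history
NULL

new_history <- function(name, final_major, final_minor, events, classes) {
  events <- as.data.frame(events)
  classes <- as.data.frame(classes)
  h <- structure(
    list(name = name,
         final_state = copy_state(final_major, final_minor),
         n_events = nrow(events),
         events = events,
         classes = classes),
    class = "evolution_history"
  )
  tot <- total_cn(h$final_state)
  stopifnot(all(h$classes$m >= 1), all(h$classes$m <= tot))
  h
}

#' @export
print.evolution_history <- function(x, ...) {
  cat(sprintf("<evolution_history> %s -> (%d,%d), %d event(s)\n",
              x$name, x$final_state$major_cn, x$final_state$minor_cn,
              x$n_events))
  cat("multiplicity classes (interval k = after event k):\n")
  print(x$classes, row.names = FALSE)
  invisible(x)
}

history_event <- function(kind, copies_added) {
  data.frame(kind = kind, copies_added = copies_added,
             stringsAsFactors = FALSE)
}

# The catalog below is hand-derived: for every path, SNVs arising in each
# interval on each copy lineage are traced through the later duplications.
history_catalog <- function() {
  list(
    copy_neutral = new_history(
      "copy_neutral", 1, 1,
      events = history_event(character(0), integer(0)),
      classes = data.frame(interval = 0L, m = 1L, copies = 2L)),

    copy_loss = new_history(
      "copy_loss", 1, 0,
      events = history_event("loss", -1L),
      # SNVs on the lost copy vanish; only the survivor accrues observable SNVs
      classes = data.frame(interval = c(0L, 1L), m = c(1L, 1L),
                           copies = c(1L, 1L))),

    cn_loh = new_history(
      "cn_loh", 2, 0,
      events = history_event("cn_loh", 0L),
      # pre-event SNVs on the retained copy are duplicated onto both copies
      classes = data.frame(interval = c(0L, 1L), m = c(2L, 1L),
                           copies = c(1L, 2L))),

    one_copy_gain = new_history(
      "one_copy_gain", 2, 1,
      events = history_event("gain", 1L),
      # pre-gain SNVs: m=2 if on the duplicated copy, m=1 on the other
      classes = data.frame(interval = c(0L, 0L, 1L), m = c(2L, 1L, 1L),
                           copies = c(1L, 1L, 3L))),

    # (3,0): two distinct 2-event paths with different class signatures
    loss_then_two_copy_gain = new_history(
      "loss_then_two_copy_gain", 3, 0,
      events = rbind(history_event("loss", -1L), history_event("gain", 2L)),
      classes = data.frame(interval = c(0L, 1L, 2L), m = c(3L, 3L, 1L),
                           copies = c(1L, 1L, 3L))),
    cn_loh_then_one_copy_gain = new_history(
      "cn_loh_then_one_copy_gain", 3, 0,
      events = rbind(history_event("cn_loh", 0L), history_event("gain", 1L)),
      classes = data.frame(interval = c(0L, 1L, 1L, 2L), m = c(3L, 2L, 1L, 1L),
                           copies = c(1L, 1L, 1L, 3L))),

    mono_allelic_two_copy_gain = new_history(
      "mono_allelic_two_copy_gain", 3, 1,
      events = history_event("gain", 2L),
      classes = data.frame(interval = c(0L, 0L, 1L), m = c(3L, 1L, 1L),
                           copies = c(1L, 1L, 4L))),
    sequential_one_copy_gains = new_history(
      "sequential_one_copy_gains", 3, 1,
      events = rbind(history_event("gain", 1L), history_event("gain", 1L)),
      # second gain duplicates one of the two copies of the gained allele
      classes = data.frame(interval = c(0L, 0L, 1L, 1L, 2L),
                           m = c(3L, 1L, 2L, 1L, 1L),
                           copies = c(1L, 1L, 1L, 2L, 4L))),

    bi_allelic_two_copy_gain = new_history(
      "bi_allelic_two_copy_gain", 2, 2,
      # both parental copies duplicated synchronously (the GD signature)
      events = history_event("gain", 2L),
      classes = data.frame(interval = c(0L, 1L), m = c(2L, 1L),
                           copies = c(2L, 4L))),

    # (4,0): the two paths distinguished by the presence of an m=3 class
    loss_then_three_copy_gain = new_history(
      "loss_then_three_copy_gain", 4, 0,
      events = rbind(history_event("loss", -1L), history_event("gain", 3L)),
      classes = data.frame(interval = c(0L, 1L, 2L), m = c(4L, 4L, 1L),
                           copies = c(1L, 1L, 4L))),
    cn_loh_then_mono_allelic_two_copy_gain = new_history(
      "cn_loh_then_mono_allelic_two_copy_gain", 4, 0,
      events = rbind(history_event("cn_loh", 0L), history_event("gain", 2L)),
      classes = data.frame(interval = c(0L, 1L, 1L, 2L),
                           m = c(4L, 3L, 1L, 1L),
                           copies = c(1L, 1L, 1L, 4L)))
  )
}

#' Enumerate candidate evolutionary histories for a copy state
#'
#' Returns every cataloged loss/gain path from (1,1) to a state with the
#' given total copy number and LOH status, each annotated with its SNV
#' multiplicity classes. Totals above 4 are refused: the path space explodes
#' and only simple representatives are meaningful there — use
#' [simple_histories()].
#'
#' @param total_cn Total copies of the final state, 1..4.
#' @param loh `TRUE` if the final state has lost all copies of one parental
#'   allele (minor copy number 0).
#' @return A list of `evolution_history` objects (possibly of length > 1 when
#'   several paths reach the same state; e.g. (4,0) is reachable by a loss
#'   followed by a three-copy gain, or by CN-LOH followed by a mono-allelic
#'   two-copy gain, distinguishable by an extra interior MAF peak).
#' @export
enumerate_histories <- function(total_cn, loh) {
  if (!is.numeric(total_cn) || length(total_cn) != 1 ||
      total_cn != round(total_cn) || total_cn < 1) {
    stop_invalid("`total_cn` must be a positive integer")
  }
  if (total_cn > 4) {
    tc_error("tc_unsupported",
             paste0("histories are only enumerated for total copy number <= 4; ",
                    "use simple_histories() for higher copy numbers"))
  }
  cat_ <- history_catalog()
  keep <- vapply(cat_, function(h) {
    tot <- total_cn(h$final_state)
    tot == total_cn && is_loh(h$final_state) == isTRUE(loh)
  }, logical(1))
  # copy_loss is the LOH state at total 1; copy_neutral the non-LOH at 2
  unname(cat_[keep])
}

#' Simple representative histories for high copy numbers
#'
#' For total copy number above 4 the number of possible paths is too large to
#' enumerate usefully; only two simple representatives are returned: a single
#' mono-allelic (total - 1)-copy gain, and — when the total is even and not
#' LOH — a maximal bi-allelic gain.
#'
#' @param total_cn Total copies of the final state (> 4).
#' @param loh Whether the final state is LOH.
#' @return A list of `evolution_history` objects.
#' @export
simple_histories <- function(total_cn, loh = FALSE) {
  if (total_cn <= 4) return(enumerate_histories(total_cn, loh))
  out <- list()
  if (loh) {
    # CN-LOH then mono-allelic (total - 2)-copy gain
    out <- c(out, list(new_history(
      sprintf("cn_loh_then_mono_allelic_%d_copy_gain", total_cn - 2L),
      total_cn, 0,
      events = rbind(history_event("cn_loh", 0L),
                     history_event("gain", total_cn - 2L)),
      classes = data.frame(
        interval = c(0L, 1L, 1L, 2L),
        m = c(total_cn, total_cn - 1L, 1L, 1L),
        copies = c(1L, 1L, 1L, total_cn)))))
  } else {
    k <- total_cn - 2L
    out <- c(out, list(new_history(
      sprintf("mono_allelic_%d_copy_gain", k), total_cn - 1L, 1L,
      events = history_event("gain", k),
      classes = data.frame(interval = c(0L, 0L, 1L),
                           m = c(k + 1L, 1L, 1L),
                           copies = c(1L, 1L, total_cn)))))
    if (total_cn %% 2L == 0L) {
      half <- total_cn %/% 2L
      out <- c(out, list(new_history(
        sprintf("bi_allelic_%d_copy_gain", total_cn - 2L), half, half,
        events = history_event("gain", total_cn - 2L),
        classes = data.frame(interval = c(0L, 1L),
                             m = c(half, 1L),
                             copies = c(2L, total_cn)))))
    }
  }
  out
}

#' Replay a history's events from the germline state
#'
#' Applies the event list starting at (1,1) and returns the resulting
#' (major, minor) state; used to check history internal consistency.
#'
#' @param h An `evolution_history`.
#' @return A [copy_state()].
#' @export
replay_history <- function(h) {
  stopifnot(inherits(h, "evolution_history"))
  major <- 1L; minor <- 1L
  if (h$n_events > 0) for (i in seq_len(h$n_events)) {
    kind <- h$events$kind[i]
    add <- h$events$copies_added[i]
    if (kind == "cn_loh") {
      minor <- 0L; major <- 2L
    } else if (kind == "loss") {
      # losses take the minor allele (the convention behind every LOH path)
      if (minor > 0L) minor <- minor - 1L else major <- major - 1L
    } else if (kind == "gain") {
      # gains amplify the major allele unless the history is bi-allelic
      if (grepl("^bi_allelic", h$name)) {
        major <- major + add %/% 2L
        minor <- minor + add %/% 2L
      } else {
        major <- major + add
      }
    }
  }
  copy_state(major, minor)
}

#' Expected MAF peaks implied by a history
#'
#' One expected peak per distinct multiplicity class of the history,
#' evaluated with [expected_maf_peak()] at the history's final state.
#'
#' @param h An `evolution_history`.
#' @param ctx A [sample_context()].
#' @param carrier_fraction Fraction of tumor cells carrying the region's
#'   altered state. When below 1 the copy change is subclonal: SNVs that
#'   arose before the first event are shared with the non-carrying tumor
#'   cells (where they sit on one copy), later ones exist in the carriers
#'   only, and all allele fractions use the mixture's average copy number.
#' @return A data frame with columns `m` (multiplicity in the carrying
#'   cells), `location` (expected MAF), `clonal` (logical:
#'   `carrier_fraction == 1`), sorted by location, deduplicated.
#' @export
peaks_for_history <- function(h, ctx, carrier_fraction = 1) {
  stopifnot(inherits(h, "evolution_history"))
  if (carrier_fraction >= 1) {
    ms <- sort(unique(h$classes$m))
    loc <- vapply(ms, function(m) {
      expected_maf_peak(ctx, h$final_state, m, 1)
    }, numeric(1))
    out <- data.frame(m = ms, location = loc, clonal = TRUE)
  } else {
    cl <- unique(h$classes[, c("interval", "m")])
    t_alt <- total_cn(h$final_state)
    loc <- vapply(seq_len(nrow(cl)), function(k) {
      m_out <- if (cl$interval[k] == 0) 1 else 0
      mixture_vaf(ctx, carrier_fraction, t_alt, ctx$normal_cn,
                  cl$m[k], m_out)
    }, numeric(1))
    out <- data.frame(m = cl$m, location = loc, clonal = FALSE)
  }
  out <- out[!duplicated(signif(out$location, 10)), , drop = FALSE]
  out[order(out$location), , drop = FALSE]
}
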