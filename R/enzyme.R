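#' Flanking-context weight tables
#'
#' An rBE's sequence-context preference is summarised by a multiplier in
#' `[0, 1]` for each of the 16 (upstream base, downstream base) pairs around
#' a substrate base. `context_weights()` builds the table from per-base
#' weights: the weight of pair (u, d) is `w(u) * w(d)`, rescaled so the
#' maximum is 1. `context_weights_uniform()` gives all-1 weights;
#' `context_weights_biased()` favours one base class over the other, e.g.
#' APOBEC1-style preference for A/U-flanked cytosines.
#'
#' @param A,C,G,T Per-base weights in `[0, 1]`.
#' @return Named numeric vector of length 16; names are the pairs
#'   `"AA", "AC", ..., "TT"` (upstream base first, DNA alphabet).
#' @examples
#' context_weights_biased(favoured = "AT", ratio = 10)
#' @export
context_weights <- function(A = 1, C = 1, G = 1, T = 1) {
  w1 <- c(A = A, C = C, G = G, T = T)
  stopifnot(all(w1 >= 0), all(w1 <= 1))
  pairs <- expand.grid(up = DNA_BASES, down = DNA_BASES,
                       stringsAsFactors = FALSE)
  w <- w1[pairs$up] * w1[pairs$down]
  w <- w / max(w)
  setNames(as.numeric(w), paste0(pairs$up, pairs$down))
}

#' @rdname context_weights
#' @export
context_weights_uniform <- function() context_weights()

#' @param favoured `"AT"` (A/U-philic) or `"GC"` (G/C-philic).
#' @param ratio Weight ratio between a fully-favoured pair (both flanks in
#'   the favoured class) and a fully-disfavoured pair.
#' @rdname context_weights
#' @export
context_weights_biased <- function(favoured = c("AT", "GC"), ratio = 10) {
  favoured <- match.arg(favoured)
  stopifnot(ratio >= 1)
  lo <- 1 / sqrt(ratio)
  if (favoured == "AT") {
    context_weights(A = 1, T = 1, C = lo, G = lo)
  } else {
    context_weights(A = lo, T = lo, C = 1, G = 1)
  }
}

context_names <- function() names(context_weights_uniform())

check_context_weights <- function(w) {
  if (is.null(w)) return(context_weights_uniform())
  if (!is.numeric(w) || length(w) != 16 ||
      !setequal(names(w), context_names())) {
    abort("`context_weights` must be a named numeric vector over the 16 flanking pairs (see context_weights()).")
  }
  if (any(w < 0 | w > 1)) abort("context weights must lie in [0, 1].")
  w[context_names()]
}

#' Generative model of an RNA base editor
#'
#' Describes how an rBE deposits edits when recruited to bound sites on a
#' transcript: the edited channel (`C2U`, `A2I`, or `DUAL` for enzymes with
#' both modalities), the peak per-read editing probability at a bound site,
#' a Gaussian distance-decay kernel of editing around the site, an
#' untargeted background rate, and flanking-context preference weights.
#'
#' The effective probability that a given substrate base is edited on a
#' given read is
#' `min(1, peak_rate * kernel(d) * context_weight) + background_rate`
#' (capped at 1), where `d` is the distance in bp from the base to the
#' midpoint of the nearest bound site assigned to the enzyme, and
#' `kernel(d) = exp(-d^2 / (2 * halfwidth^2))`, truncated to 0 beyond
#' `4 * halfwidth`.
#'
#' For `edit_type = "DUAL"`, scalar parameters apply to both channels;
#' length-2 vectors named `c(C2U = , A2I = )` set them per channel.
#'
#' @param name Enzyme label.
#' @param edit_type `"C2U"`, `"A2I"` or `"DUAL"`.
#' @param peak_rate Peak per-read editing probability at a bound site.
#' @param kernel_halfwidth Distance-decay scale in bp.
#' @param background_rate Per-read, per-substrate-base off-target editing
#'   probability.
#' @param context_weights Named length-16 vector from [context_weights()],
#'   or `NULL` for uniform; for DUAL models, optionally a list of two such
#'   vectors named `C2U` and `A2I`.
#' @return An object of class `enzyme_model`.
#' @examples
#' apo <- enzyme_model("APOBEC1", "C2U", peak_rate = 0.3,
#'                     kernel_halfwidth = 25, background_rate = 1e-3,
#'                     context_weights = context_weights_biased("AT", 10))
#' enzyme_channels(apo)
#' @export
enzyme_model <- function(name, edit_type = c("C2U", "A2I", "DUAL"),
                         peak_rate = 0.3, kernel_halfwidth = 25,
                         background_rate = 0,
                         context_weights = NULL) {
  edit_type <- match.arg(edit_type)
  channels <- if (edit_type == "DUAL") c("C2U", "A2I") else edit_type
  pick <- function(x, ch, what) {
    if (length(x) == 1) return(unname(x))
    if (!is.null(names(x)) && ch %in% names(x)) return(unname(x[[ch]]))
    abort(paste0("`", what, "` must be scalar or named per channel."))
  }
  pick_w <- function(w, ch) {
    if (is.list(w) && !is.null(names(w))) w <- w[[ch]]
    check_context_weights(w)
  }
  chan <- lapply(channels, function(ch) {
    pr <- pick(peak_rate, ch, "peak_rate")
    bg <- pick(background_rate, ch, "background_rate")
    hw <- pick(kernel_halfwidth, ch, "kernel_halfwidth")
    if (pr < 0 || pr > 1 || bg < 0 || bg > 1) {
      abort("rates must lie in [0, 1].")
    }
    if (hw <= 0) abort("`kernel_halfwidth` must be positive.")
    list(edit_type = ch, peak_rate = pr, kernel_halfwidth = hw,
         background_rate = bg, context_weights = pick_w(context_weights, ch))
  })
  structure(list(name = name, edit_type = edit_type, channels = chan),
            class = "enzyme_model")
}

#' @export
print.enzyme_model <- function(x, ...) {
  cat("<enzyme_model> ", x$name, " [", x$edit_type, "]\n", sep = "")
  for (ch in x$channels) {
    cat(sprintf("  %s: peak_rate=%g halfwidth=%gbp background=%g\n",
                ch$edit_type, ch$peak_rate, ch$kernel_halfwidth,
                ch$background_rate))
  }
  invisible(x)
}

#' Channel table of an enzyme model
#'
#' @param enzyme An [enzyme_model()].
#' @return A tibble with one row per editing channel (`C2U` and/or `A2I`)
#'   and a `context_weights` list-column.
#' @export
enzyme_channels <- function(enzyme) {
  stopifnot(inherits(enzyme, "enzyme_model"))
  tibble(
    enzyme = enzyme$name,
    edit_type = vapply(enzyme$channels, `[[`, character(1), "edit_type"),
    peak_rate = vapply(enzyme$channels, `[[`, numeric(1), "peak_rate"),
    kernel_halfwidth = vapply(enzyme$channels, `[[`, numeric(1),
                              "kernel_halfwidth"),
    background_rate = vapply(enzyme$channels, `[[`, numeric(1),
                             "background_rate"),
    context_weights = lapply(enzyme$channels, `[[`, "context_weights")
  )
}

#' Gaussian recruitment kernel
#'
#' @param d Distance in bp (numeric vector).
#' @param halfwidth Decay scale in bp.
#' @return Kernel values in `[0, 1]`; 0 beyond `4 * halfwidth`.
#' @export
recruitment_kernel <- function(d, halfwidth) {
  stopifnot(halfwidth > 0)
  k <- exp(-d^2 / (2 * halfwidth^2))
  k[abs(d) > 4 * halfwidth] <- 0
  k
}

#' Substrate reference base of an editing channel (sense strand)
#' @noRd
substrate_base <- function(edit_type) {
  switch(edit_type, C2U = "C", A2I = "A",
         abort(paste0("unknown edit_type: ", edit_type)))
}

#' Read-level product base of an editing channel (sense strand)
#' @noRd
product_base <- function(edit_type) {
  switch(edit_type, C2U = "T", A2I = "G",
         abort(paste0("unknown edit_type: ", edit_type)))
}
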