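#' Stem-loop cassette sequences
#'
#' Fixed hairpin sequences (DNA alphabet) standing in for the MS2 and PP7
#' coat-protein binding loops used on tethering reporters. Only the loop
#' coordinates matter to downstream analyses, so any fixed hairpin of
#' representative length serves.
#' @noRd
MS2_LOOP <- "ACATGAGGATCACCCATGT"
PP7_LOOP <- "GGCACAGAAGATATGGCTTCGTGCC"

loop_seq <- function(kind) switch(kind, MS2 = MS2_LOOP, PP7 = PP7_LOOP)

#' Build a tethering-reporter construct
#'
#' Assembles an editable reporter mRNA: a GFP-length coding sequence
#' followed by a 3'UTR carrying MS2 and/or PP7 stem-loops that recruit
#' coat-protein-rBE fusions. Four layouts are supported:
#'
#' * `MS2x12` — twelve MS2 loops separated by 50-bp linkers (the classic
#'   single-editor screen reporter);
#' * `PAIRED_350` — two MS2/PP7 pairs, the loops of a pair 50 bp apart and
#'   350 bp separating the pairs (dual-editor proximity reporter);
#' * `ALT12` / `ALT4` — twelve or four alternating MS2/PP7 loops spaced
#'   50 bp apart (dual-editor alternating reporters).
#'
#' @param layout_name One of `"MS2x12"`, `"PAIRED_350"`, `"ALT12"`, `"ALT4"`.
#' @param seed Integer seed; the construct sequence is deterministic given
#'   the seed (linker/CDS bases are drawn from it).
#' @param cds_length Length of the GFP stand-in CDS in bp.
#' @param gc GC content of the random CDS/linker sequence.
#' @return An object of class `reporter_spec`: a list with `name`,
#'   `cds_seq`, `utr_layout` (tibble of elements `kind`, `length`),
#'   `full_seq`, and `loop_intervals` (tibble `kind`, `start`, `end`;
#'   0-based half-open coordinates on `full_seq`).
#' @examples
#' rep12 <- build_reporter("MS2x12", seed = 1)
#' nrow(rep12$loop_intervals)  # 12
#' @export
build_reporter <- function(layout_name, seed = 1L, cds_length = 720,
                           gc = 0.45) {
  layouts <- c("MS2x12", "PAIRED_350", "ALT12", "ALT4")
  if (!is.character(layout_name) || length(layout_name) != 1 ||
      !layout_name %in% layouts) {
    abort(paste0("unknown reporter layout: ",
                 paste(layout_name, collapse = ","),
                 " (expected one of ", paste(layouts, collapse = ", "), ")"),
          class = "stamper_config_error")
  }
  kinds <- switch(layout_name,
    MS2x12     = rep("MS2", 12),
    PAIRED_350 = c("MS2", "PP7", "MS2", "PP7"),
    ALT12      = rep(c("MS2", "PP7"), 6),
    ALT4       = rep(c("MS2", "PP7"), 2))
  # linker following each loop; PAIRED_350 separates the two pairs by 350 bp
  gaps <- switch(layout_name,
    PAIRED_350 = c(50, 350, 50, 50),
    rep(50, length(kinds)))

  layout <- tibble(kind = "linker", length = 50)  # lead-in linker
  for (i in seq_along(kinds)) {
    layout <- bind_rows(layout,
      tibble(kind = kinds[i], length = nchar(loop_seq(kinds[i]))),
      tibble(kind = "linker", length = gaps[i]))
  }

  with_seed(seed, {
    cds <- paste0("ATG", random_dna(cds_length - 6, gc), "TAA")
    pieces <- purrr::map_chr(seq_len(nrow(layout)), function(i) {
      k <- layout$kind[i]
      if (k == "linker") random_dna(layout$length[i], gc) else loop_seq(k)
    })
    utr <- paste(pieces, collapse = "")
  })

  ends <- nchar(cds) + cumsum(layout$length)
  starts <- ends - layout$length
  is_loop <- layout$kind != "linker"
  loops <- tibble(kind = layout$kind[is_loop],
                  start = starts[is_loop], end = ends[is_loop])

  structure(list(
    name = layout_name,
    cds_seq = cds,
    utr_layout = layout,
    full_seq = paste0(cds, utr),
    loop_intervals = loops
  ), class = "reporter_spec")
}

#' @export
print.reporter_spec <- function(x, ...) {
  cat("<reporter_spec> ", x$name, ": ", nchar(x$full_seq), " bp (CDS ",
      nchar(x$cds_seq), " bp, ", nrow(x$loop_intervals), " loops: ",
      paste(x$loop_intervals$kind, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Region annotation of a reporter construct
#'
#' @param spec A [build_reporter()] object.
#' @return Tibble with `region` (`CDS`, `UTR3`), `start`, `end` (0-based
#'   half-open).
#' @export
reporter_regions <- function(spec) {
  stopifnot(inherits(spec, "reporter_spec"))
  cds_len <- nchar(spec$cds_seq)
  tibble(region = c("CDS", "UTR3"),
         start = c(0L, cds_len),
         end = c(cds_len, nchar(spec$full_seq)))
}

#' Bound-site intervals of a reporter for a set of tethered enzymes
#'
#' Maps loop kinds to the enzymes recruited to them (via coat-protein
#' fusions), producing the bound-site table [simulate_reads()] consumes.
#'
#' @param spec A [build_reporter()] object.
#' @param ... Named arguments `MS2 = "enzyme name"`, `PP7 = "enzyme name"`;
#'   loop kinds without an enzyme are left untethered.
#' @param ref Reference name of the construct (default the layout name).
#' @return Tibble `ref`, `start`, `end`, `enzyme` (0-based half-open).
#' @examples
#' sp <- build_reporter("ALT4", seed = 1)
#' reporter_bound_sites(sp, MS2 = "MCP-APOBEC1", PP7 = "PP7CP-8e")
#' @export
reporter_bound_sites <- function(spec, ..., ref = spec$name) {
  stopifnot(inherits(spec, "reporter_spec"))
  map <- list(...)
  keep <- spec$loop_intervals$kind %in% names(map)
  li <- spec$loop_intervals[keep, , drop = FALSE]
  tibble(ref = ref, start = li$start, end = li$end,
         enzyme = unlist(map[li$kind], use.names = FALSE) %||% character(0))
}
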