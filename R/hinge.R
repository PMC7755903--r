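# Hinge-wingspan ("molecular pliers") geometric model.
#
# A bivalent IgG bridging two diagonally opposed protomers of the
# beta-tryptase tetramer must span a fixed inter-anchor distance (51 A
# between the two Fab C-termini in the crystal structure).  The two upper
# hinges together span ~4.2 A per residue relaxed and 1.5x that fully
# elongated; an IgG whose relaxed span already covers the anchors feels no
# strain (no dissociation), while one whose tense span cannot reach them
# cannot bind bivalently at all.  Inhibition requires reach *with* residual
# strain.

#' Geometric parameters of the hinge-span model
#'
#' @param L_ref Relaxed span of one reference upper hinge, in Angstrom.
#'   The 10-residue IgG1 upper hinge spans 21 A, i.e. 2.1 A per residue.
#'   Set `L_ref = 20` to recover the looser 2 A-per-residue reading.
#' @param n_ref Residue count of the reference hinge.
#' @param f_tense Ratio of the fully elongated (tense) to the relaxed
#'   per-residue span; 3 A vs 2 A gives the default 1.5.
#' @param d_req Required inter-anchor reach in Angstrom (Fab C-terminus to
#'   Fab C-terminus across the tetramer diagonal).
#' @param eps Reach/strain tolerance in Angstrom.  A variant reaches if its
#'   tense span comes within `eps` of `d_req`, and is classified as only
#'   marginally strained when its relaxed span is within `eps` of `d_req`.
#'
#' @return An object of class `geometry_params`.
#' @export
geometry_params <- function(L_ref = 21, n_ref = 10, f_tense = 1.5,
                            d_req = 51, eps = 1.0) {
  stopifnot(is.numeric(L_ref), L_ref > 0,
            is.numeric(n_ref), n_ref >= 1,
            is.numeric(f_tense), f_tense >= 1,
            is.numeric(d_req), d_req >= 0,
            is.numeric(eps), eps >= 0)
  structure(list(L_ref = L_ref, n_ref = n_ref, f_tense = f_tense,
                 d_req = d_req, eps = eps),
            class = "geometry_params")
}

#' An upper-hinge variant
#'
#' @param name Variant label.
#' @param upper_seq One-letter amino-acid string of the upper hinge.
#'   Alignment gap dashes (`-`) are stripped before counting.
#' @param constrained Logical; TRUE when the two upper hinges are tethered
#'   to each other (IgG2-like or engineered inter-hinge cysteines).
#' @param scaffold Isotype scaffold label (`"IgG1"`, `"IgG2"`, `"IgG4"`).
#'
#' @return An object of class `hinge_variant` with fields `name`,
#'   `upper_seq`, `n` (residue count), `constrained`, `scaffold` and a
#'   `degenerate` flag for empty hinges.
#' @export
hinge_variant <- function(name, upper_seq, constrained = FALSE,
                          scaffold = "IgG1") {
  seq <- gsub("-", "", toupper(upper_seq), fixed = TRUE)
  if (nzchar(seq)) aa_chars(seq, paste0("upper_seq of ", name))
  stop_if_not_flag(constrained, "constrained")
  structure(list(name = as.character(name), upper_seq = seq,
                 n = nchar(seq), constrained = constrained,
                 scaffold = as.character(scaffold),
                 degenerate = !nzchar(seq)),
            class = "hinge_variant")
}

#' Load hinge variants from a delimited table
#'
#' Reads a CSV/TSV (or takes a data.frame) with columns `name`,
#' `upper_seq`, `constrained` and optionally `scaffold`, and builds one
#' [hinge_variant()] per row.  When `infer_constraint = TRUE` a row whose
#' hinge carries more cysteines than the scaffold baseline (one for IgG1)
#' is flagged constrained even if its `constrained` column says otherwise;
#' by default the explicit column is authoritative.
#'
#' @param table Path to a delimited file, or a data.frame.
#' @param sep Field separator; guessed from the file extension when `NULL`.
#' @param infer_constraint Logical, see Description.
#' @param cys_baseline Cysteine count of the unconstrained scaffold hinge.
#'
#' @return A list of `hinge_variant` objects.
#' @export
load_variants <- function(table, sep = NULL, infer_constraint = FALSE,
                          cys_baseline = 1L) {
  if (is.character(table)) {
    if (is.null(sep)) {
      sep <- if (grepl("\\.tsv$|\\.txt$", table, ignore.case = TRUE)) "\t" else ","
    }
    table <- utils::read.table(table, sep = sep, header = TRUE,
                               stringsAsFactors = FALSE,
                               colClasses = "character")
  }
  if (!is.data.frame(table)) stop("table must be a file path or data.frame")
  needed <- c("name", "upper_seq", "constrained")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    stop("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"scaffold" %in% names(table)) table$scaffold <- "IgG1"
  out <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    con <- row$constrained
    if (is.character(con)) {
      con <- switch(tolower(trimws(con)),
                    "true" = TRUE, "t" = TRUE, "1" = TRUE, "yes" = TRUE,
                    "false" = FALSE, "f" = FALSE, "0" = FALSE, "no" = FALSE,
                    NA)
    }
    if (is.na(con)) stop("row ", i, ": constrained not parseable as boolean")
    v <- tryCatch(
      hinge_variant(row$name, row$upper_seq, isTRUE(con), row$scaffold),
      error = function(e) stop("row ", i, ": ", conditionMessage(e), call. = FALSE)
    )
    if (infer_constraint && !v$constrained) {
      n_cys <- sum(strsplit(v$upper_seq, "")[[1]] == "C")
      if (n_cys > cys_baseline) v$constrained <- TRUE
    }
    out[[i]] <- v
  }
  out
}

#' Hinge span in Angstrom
#'
#' Relaxed one-arm span is `L_ref * n / n_ref`; the tense span multiplies
#' by `f_tense`; `arms = "both"` doubles the one-arm value.  Vectorised
#' over `n`.
#'
#' @param n Residue count(s) of the upper hinge.
#' @param mode `"relaxed"` or `"tense"`.
#' @param arms `"one"` or `"both"`.
#' @param params A [geometry_params()] object.
#'
#' @return Span(s) in Angstrom.
#' @export
hinge_span <- function(n, mode = c("relaxed", "tense"),
                       arms = c("one", "both"), params = geometry_params()) {
  mode <- match.arg(mode)
  arms <- match.arg(arms)
  if (any(n < 0)) stop("negative residue count")
  span <- params$L_ref * n / params$n_ref
  if (mode == "tense") span <- span * params$f_tense
  if (arms == "both") span <- span * 2
  span
}

#' Assess reach and strain of a hinge variant
#'
#' @param variant A [hinge_variant()] or a bare residue count.
#' @param params A [geometry_params()] object.
#'
#' @return A `span_assessment` list with `relaxed_both`, `tense_both`
#'   (two-hinge spans, A), `strain_ratio` (position of `d_req` within the
#'   relaxed-tense bracket, `NA` when `d_req` lies outside it), `reach_ok`
#'   (tense span reaches `d_req` within `eps`) and `strain_ok` (relaxed
#'   span does not already cover `d_req` beyond `eps`).
#' @export
assess_span <- function(variant, params = geometry_params()) {
  n <- if (inherits(variant, "hinge_variant")) variant$n else variant
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  relaxed_both <- hinge_span(n, "relaxed", "both", params)
  tense_both <- hinge_span(n, "tense", "both", params)
  reach_ok <- tense_both + params$eps >= params$d_req
  strain_ok <- relaxed_both <= params$d_req + params$eps
  strain_ratio <- NA_real_
  if (reach_ok && strain_ok && tense_both > relaxed_both &&
      params$d_req >= relaxed_both && params$d_req <= tense_both) {
    strain_ratio <- (params$d_req - relaxed_both) / (tense_both - relaxed_both)
  }
  structure(list(n = n, relaxed_both = relaxed_both, tense_both = tense_both,
                 strain_ratio = strain_ratio, reach_ok = reach_ok,
                 strain_ok = strain_ok),
            class = "span_assessment")
}

#' Predict the inhibition class of a hinge variant
#'
#' Classification: a constrained hinge cannot strain (`none/constrained`);
#' a hinge whose tense span cannot reach the anchors cannot bind
#' bivalently (`none/no_reach`); one whose relaxed span already covers
#' them binds without strain (`none/no_strain`); a relaxed span within
#' `eps` of the requirement yields only marginal strain (`partial`);
#' otherwise the bridged IgG is strained and dissociates the tetramer
#' (`full`).  The span calibration is anchored on the IgG1 scaffold;
#' unconstrained variants on other scaffolds return class `NA` with reason
#' `unsupported_scaffold` unless `allow_cross_scaffold = TRUE`.
#'
#' @param variant A [hinge_variant()].
#' @param params A [geometry_params()] object.
#' @param allow_cross_scaffold Apply the IgG1 calibration to other
#'   scaffolds anyway (off by default; see the methods vignette).
#'
#' @return An `inhibition_prediction` list with `class` (one of `full`,
#'   `partial`, `none`, or `NA`) and `reason`.
#' @export
predict_inhibition <- function(variant, params = geometry_params(),
                               allow_cross_scaffold = FALSE) {
  stopifnot(inherits(variant, "hinge_variant"))
  mk <- function(class, reason) {
    structure(list(name = variant$name, class = class, reason = reason),
              class = "inhibition_prediction")
  }
  if (variant$constrained) return(mk("none", "constrained"))
  if (!identical(variant$scaffold, "IgG1") && !allow_cross_scaffold) {
    return(mk(NA_character_, "unsupported_scaffold"))
  }
  a <- assess_span(variant, params)
  if (!a$reach_ok) return(mk("none", "no_reach"))
  if (!a$strain_ok) return(mk("none", "no_strain"))
  if (abs(params$d_req - a$relaxed_both) <= params$eps) {
    return(mk("partial", "marginal_strain"))
  }
  mk("full", "strained_ok")
}

#' Scan hinge lengths for the active window
#'
#' Classifies an unconstrained IgG1-scaffold hinge at every length in
#' `n_range` and reports the predicted class for each.
#'
#' @param params A [geometry_params()] object.
#' @param n_range Integer vector of hinge lengths to scan.
#'
#' @return A data.frame with columns `n`, `relaxed_both`, `tense_both`,
#'   `class`, `reason` and logical `active` (class full or partial).
#' @export
scan_active_window <- function(params = geometry_params(), n_range = 4:20) {
  if (!length(n_range)) stop("n_range is empty")
  rows <- lapply(as.integer(n_range), function(n) {
    v <- structure(list(name = paste0("n", n), upper_seq = strrep("G", n),
                        n = n, constrained = FALSE, scaffold = "IgG1",
                        degenerate = n == 0L),
                   class = "hinge_variant")
    p <- predict_inhibition(v, params)
    a <- assess_span(v, params)
    data.frame(n = n, relaxed_both = a$relaxed_both,
               tense_both = a$tense_both, class = p$class,
               reason = p$reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$active <- !is.na(out$class) & out$class %in% c("full", "partial")
  out
}

#' @export
print.span_assessment <- function(x, ...) {
  cat(sprintf("hinge span (n = %d): relaxed %.1f A, tense %.1f A\n",
              x$n, x$relaxed_both, x$tense_both))
  cat(sprintf("  reach_ok: %s, strain_ok: %s, strain ratio: %s\n",
              x$reach_ok, x$strain_ok,
              ifelse(is.na(x$strain_ratio), "undefined",
                     sprintf("%.3f", x$strain_ratio))))
  invisible(x)
}

#' @export
print.inhibition_prediction <- function(x, ...) {
  cat(sprintf("%s: %s (%s)\n", x$name,
              ifelse(is.na(x$class), "out of model", x$class), x$reason))
  invisible(x)
}
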