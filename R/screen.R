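## The cysteine cross-linking screen: position selection by heptad
## register, per-residue efficiency tables, axial-residue calling.

#' Construct a cross-linking efficiency table
#'
#' One row per screened residue position (protein numbering of the
#' screened species). Efficiency is the fraction of cross-linked over
#' total protein species; untested positions carry `NA` efficiency.
#'
#' @param position integer residue numbers, unique.
#' @param efficiency fractions in \[0, 1\]; `NA` where untested.
#' @param tested logical; defaults to `!is.na(efficiency)`.
#' @param helix_label optional per-position label, e.g. `"N-coil"`,
#'   `"C-coil"`, `"head"`, `"hinge"`, `"joint"`.
#' @param protein_id free-text identifier of the screened protein.
#' @param replicate free-text replicate metadata.
#' @return object of class `crosslink_table` (a data frame sorted by
#'   position, with attributes `protein_id` and `replicate`).
#' @export
crosslink_table <- function(position, efficiency, tested = !is.na(efficiency),
                            helix_label = NA_character_,
                            protein_id = "", replicate = "") {
  position <- as.integer(position)
  if (anyDuplicated(position)) stopf("duplicate positions in cross-link table")
  efficiency <- as.numeric(efficiency)
  if (any(tested & is.na(efficiency))) stopf("tested positions must carry an efficiency")
  if (any(!tested & !is.na(efficiency))) stopf("untested positions must not carry an efficiency")
  bad <- which(!is.na(efficiency) & (efficiency < 0 | efficiency > 1))
  if (length(bad)) {
    stopf("efficiency outside [0, 1] at position(s) %s",
          paste(position[bad], collapse = ", "))
  }
  tab <- data.frame(position = position, efficiency = efficiency,
                    tested = as.logical(tested),
                    helix_label = rep_len(as.character(helix_label), length(position)),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$position), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "protein_id") <- protein_id
  attr(tab, "replicate") <- replicate
  class(tab) <- c("crosslink_table", "data.frame")
  tab
}

#' Read a cross-linking efficiency table from delimited text
#'
#' The file must declare its efficiency units: either a comment line
#' `# units: percent` / `# units: fraction` before the header, or a column
#' named `efficiency_percent` / `efficiency_fraction`. Units are never
#' guessed from the values. Percent input is normalized to fractions.
#' Positions with an empty/NA efficiency are recorded as untested.
#'
#' @param path TSV or CSV file with columns `position`, `efficiency`
#'   (or a unit-suffixed variant) and optional `helix_label`.
#' @param sep field separator; `NULL` infers TSV vs CSV from the extension.
#' @return a [crosslink_table()].
#' @export
load_efficiency_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(sep)) sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  lines <- readLines(path)
  comment <- grep("^#", lines, value = TRUE)
  units <- NA_character_
  um <- regmatches(comment, regexpr("units:\\s*(percent|fraction)", comment))
  if (length(um)) units <- sub("units:\\s*", "", um[1])
  df <- read.table(text = lines, sep = sep, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  eff_col <- intersect(c("efficiency", "efficiency_percent", "efficiency_fraction"),
                       names(df))
  if (!length(eff_col)) stopf("no efficiency column in %s", path)
  eff_col <- eff_col[1]
  if (eff_col == "efficiency_percent") units <- "percent"
  if (eff_col == "efficiency_fraction") units <- "fraction"
  if (is.na(units)) {
    stopf("%s does not declare efficiency units (add '# units: percent|fraction' or use a unit-suffixed column name)", path)
  }
  if (!"position" %in% names(df)) stopf("no 'position' column in %s", path)
  pos <- suppressWarnings(as.integer(df$position))
  eff <- suppressWarnings(as.numeric(df[[eff_col]]))
  bad_rows <- which(is.na(pos) | (!is.na(df[[eff_col]]) & df[[eff_col]] != "" & is.na(eff)))
  if (length(bad_rows)) {
    stopf("malformed row(s) %s in %s", paste(bad_rows, collapse = ", "), path)
  }
  if (anyDuplicated(pos)) {
    stopf("duplicate position(s) %s in %s",
          paste(unique(pos[duplicated(pos)]), collapse = ", "), path)
  }
  hi <- if (units == "percent") 100 else 1
  out_of_range <- which(!is.na(eff) & (eff < 0 | eff > hi))
  if (length(out_of_range)) {
    stopf("efficiency outside [0, %g] at row(s) %s", hi,
          paste(out_of_range, collapse = ", "))
  }
  if (units == "percent") eff <- eff / 100
  crosslink_table(pos, eff,
                  helix_label = if ("helix_label" %in% names(df)) df$helix_label else NA,
                  protein_id = if ("protein_id" %in% names(df)) df$protein_id[1] else "")
}

#' Write a cross-linking efficiency table
#'
#' Always writes fractions, with a `# units: fraction` declaration so the
#' file round-trips through [load_efficiency_table()].
#'
#' @param table a [crosslink_table()].
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
save_efficiency_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# units: fraction", con)
  write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Assign heptad register letters from anchored segments
#'
#' Coiled-coil residues are labeled a-g cyclically; the screen excludes
#' core `a`/`d` positions. Register is configuration, not prediction: each
#' segment carries one anchor residue with a known letter and the letters
#' propagate cyclically inside the segment. Letters are independent across
#' segments, so register breaks (e.g. at the joint) are expressed as
#' segment boundaries.
#'
#' @param segments data frame with columns `start`, `end`,
#'   `anchor_position`, `anchor_letter` (one of a-g); segments must not
#'   overlap and anchors must lie inside their segments.
#' @return object of class `heptad_assignment`.
#' @export
assign_register <- function(segments) {
  segments <- as.data.frame(segments)
  need <- c("start", "end", "anchor_position", "anchor_letter")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stopf("segments missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(segments$anchor_letter %in% letters[1:7])) {
    stopf("anchor_letter must be one of a-g")
  }
  if (any(segments$anchor_position < segments$start |
          segments$anchor_position > segments$end)) {
    stopf("anchor outside its segment")
  }
  seg <- segments[order(segments$start), , drop = FALSE]
  if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
    stopf("overlapping register segments")
  }
  structure(list(segments = seg), class = "heptad_assignment")
}

#' Heptad letter of residue positions
#' @param register a [assign_register()] result.
#' @param positions integer residue numbers.
#' @return character vector of letters a-g, `NA` outside all segments.
#' @export
register_letter <- function(register, positions) {
  out <- rep(NA_character_, length(positions))
  for (i in seq_len(nrow(register$segments))) {
    s <- register$segments[i, ]
    inside <- positions >= s$start & positions <= s$end
    if (!any(inside)) next
    anchor_idx <- match(s$anchor_letter, letters[1:7]) - 1L
    off <- (positions[inside] - s$anchor_position + anchor_idx) %% 7L
    out[inside] <- letters[1:7][off + 1L]
  }
  out
}

#' Screen-position selection: non-core residues in a range
#'
#' Returns the residues in `from:to` whose heptad letter is not `a` or `d`
#' (the hydrophobic core, unavailable for surface cysteine cross-linking).
#'
#' @param register a [assign_register()] result.
#' @param from,to residue range (inclusive).
#' @return integer vector of candidate positions (5 of every 7 within
#'   assigned segments); positions outside all segments are dropped with a
#'   warning.
#' @export
select_screen_positions <- function(register, from, to) {
  positions <- seq.int(from, to)
  letter <- register_letter(register, positions)
  if (anyNA(letter)) {
    warnf("%d position(s) in %d-%d are outside assigned register segments",
          sum(is.na(letter)), from, to)
  }
  positions[!is.na(letter) & !letter %in% c("a", "d")]
}

#' Call axial residues from a cross-link table
#'
#' Axial residues are those lying on the rod's two-fold axis, operationally
#' defined by strong in-vivo cross-linking: efficiency strictly greater
#' than the threshold (default > 0.20, i.e. >20\% cross-linked dimers).
#'
#' @param table a [crosslink_table()].
#' @param threshold efficiency threshold (fraction), strict inequality.
#' @return sorted integer vector of axial positions.
#' @export
call_axial <- function(table, threshold = 0.20) {
  if (!nrow(table)) stopf("empty cross-link table")
  sort(table$position[table$tested & !is.na(table$efficiency) &
                        table$efficiency > threshold])
}

#' Bin a cross-linking efficiency into the display classes
#'
#' Four classes (none/low/medium/high) matching the usual blue/yellow/
#' orange/red residue coloring. The bin edges are package defaults chosen
#' so that "strong" (> 0.20) spans medium plus high; they are display
#' conventions, configurable, not measured quantities.
#'
#' @param efficiency numeric fractions in \[0, 1\].
#' @param breaks ascending bin edges `c(none|low, low|medium, medium|high)`.
#' @return factor with levels none, low, medium, high.
#' @export
classify_efficiency <- function(efficiency, breaks = c(0.05, 0.20, 0.40)) {
  if (any(!is.na(efficiency) & (efficiency < 0 | efficiency > 1))) {
    stopf("efficiency outside [0, 1]")
  }
  cut(efficiency, breaks = c(-Inf, breaks, Inf), right = FALSE,
      labels = c("none", "low", "medium", "high"))
}
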