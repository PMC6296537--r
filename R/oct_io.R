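# Data model and I/O for polar OCT frames, region masks, observer readings,
# and tabular outputs.
#
# The polar domain is canonical throughout the package: rows are A-lines,
# columns are depth samples, with sample index 0 at the catheter. Depth of
# sample j (0-based) is j * axial_pitch_mm. All estimation happens in this
# domain; scan conversion to Cartesian display is out of scope.

#' Construct a polar OCT frame
#'
#' @param intensity numeric matrix, rows = A-lines, columns = depth samples,
#'   native grayscale units (finite, >= 0).
#' @param axial_pitch_mm depth spacing per sample, millimetres (> 0).
#' @param catheter_offset 0-based index of the first tissue-usable depth
#'   sample; samples before it belong to the catheter interior and are used
#'   only for noise-floor estimation.
#' @param frame_id,patient_id identifier strings.
#' @return an object of class `polar_frame`.
#' @export
polar_frame <- function(intensity, axial_pitch_mm, catheter_offset = 0L,
                        frame_id = "frame1", patient_id = "patient1") {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    abort_validation("intensity must be a numeric matrix")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    abort_validation("intensities must be finite and >= 0")
  stopifnot_scalar_number(axial_pitch_mm, "axial_pitch_mm")
  if (axial_pitch_mm <= 0) abort_validation("axial_pitch_mm must be > 0")
  catheter_offset <- as.integer(catheter_offset)
  if (catheter_offset < 0L || catheter_offset >= ncol(intensity))
    abort_validation("catheter_offset must satisfy 0 <= offset < n_depth")
  structure(list(intensity = intensity,
                 axial_pitch_mm = axial_pitch_mm,
                 catheter_offset = catheter_offset,
                 frame_id = as.character(frame_id),
                 patient_id = as.character(patient_id)),
            class = "polar_frame")
}

#' @export
print.polar_frame <- function(x, ...) {
  cat(sprintf("<polar_frame %s/%s: %d A-lines x %d depth samples, pitch %.4g mm, offset %d>\n",
              x$patient_id, x$frame_id, nrow(x$intensity), ncol(x$intensity),
              x$axial_pitch_mm, x$catheter_offset))
  invisible(x)
}

#' @export
dim.polar_frame <- function(x) dim(x$intensity)

read_sidecar <- function(sidecar_path) {
  if (!file.exists(sidecar_path)) abort_config("missing sidecar file: ", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (key in c("axial_pitch_mm", "catheter_offset"))
    if (is.null(meta[[key]]))
      abort_config("sidecar ", sidecar_path, " is missing required key '", key, "'")
  meta
}

#' Read an OCT pullback from a TIFF stack plus JSON sidecar
#'
#' The sidecar must declare `axial_pitch_mm` and `catheter_offset`; it may also
#' carry `patient_id` and per-page `frame_ids`. Page order is preserved.
#'
#' @param frame_stack_path multi-page grayscale TIFF.
#' @param sidecar_path JSON metadata sidecar.
#' @return list of [polar_frame()] objects (possibly empty, with a warning).
#' @export
read_pullback <- function(frame_stack_path, sidecar_path) {
  meta <- read_sidecar(sidecar_path)
  pages <- read_tiff_stack(frame_stack_path)
  if (length(pages) == 0L) return(list())
  dims <- vapply(pages, dim, integer(2L))
  if (any(dims != dims[, 1L]))
    abort_format("pages of ", frame_stack_path, " differ in shape")
  ids <- meta$frame_ids %||% sprintf("frame%03d", seq_along(pages))
  if (length(ids) != length(pages))
    abort_format("sidecar lists ", length(ids), " frame_ids for ",
                 length(pages), " pages")
  lapply(seq_along(pages), function(i)
    polar_frame(pages[[i]], meta$axial_pitch_mm, meta$catheter_offset,
                frame_id = ids[i], patient_id = meta$patient_id %||% "patient1"))
}

#' Write an OCT pullback as a TIFF stack plus JSON sidecar
#'
#' @param frames list of [polar_frame()] objects sharing metadata.
#' @param frame_stack_path,sidecar_path output paths.
#' @param bits TIFF bit depth (integer frames round-trip exactly at 16).
#' @return `frame_stack_path`, invisibly.
#' @export
write_pullback <- function(frames, frame_stack_path, sidecar_path, bits = 16L) {
  pages <- lapply(frames, function(f) f$intensity)
  write_tiff_stack(pages, frame_stack_path, bits = bits)
  meta <- list(
    axial_pitch_mm = if (length(frames)) frames[[1L]]$axial_pitch_mm else 0.005,
    catheter_offset = if (length(frames)) frames[[1L]]$catheter_offset else 0L,
    patient_id = if (length(frames)) frames[[1L]]$patient_id else "patient1",
    frame_ids = vapply(frames, `[[`, character(1L), "frame_id"))
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(frame_stack_path)
}

#' Construct a region-of-interest mask bound to a frame
#'
#' Connected fragments are labelled with 8-connectivity, matching free-hand
#' tracing of contiguous blobs.
#'
#' @param member logical matrix congruent with the frame it annotates.
#' @param frame_id identifier of the annotated frame.
#' @return an object of class `region_mask` with `fragment_labels` (integer
#'   matrix, 0 = background) and `n_fragments`.
#' @export
region_mask <- function(member, frame_id = "frame1") {
  if (!is.matrix(member) || !is.logical(member))
    abort_validation("member must be a logical matrix")
  lab <- label_fragments(member)
  structure(list(member = member, frame_id = as.character(frame_id),
                 fragment_labels = lab, n_fragments = max(lab)),
            class = "region_mask")
}

#' Label 8-connected fragments of a binary mask
#'
#' Run-based two-pass labelling: maximal horizontal runs per A-line are linked
#' across adjacent rows when they overlap under 8-connectivity, then merged by
#' union-find. Labels are renumbered 1..k in order of first appearance.
#'
#' @param member logical matrix.
#' @return integer matrix of the same shape; 0 where not a member.
#' @export
label_fragments <- function(member) {
  nr <- nrow(member); nc <- ncol(member)
  lab <- matrix(0L, nr, nc)
  runs <- vector("list", nr)   # per row: matrix with columns (start, end, run_id)
  id <- 0L
  for (i in seq_len(nr)) {
    d <- diff(c(FALSE, member[i, ], FALSE))
    starts <- which(d == 1L); ends <- which(d == -1L) - 1L
    if (length(starts)) {
      ids <- id + seq_along(starts)
      id <- id + length(starts)
      runs[[i]] <- cbind(starts, ends, ids)
    }
  }
  if (id == 0L) return(lab)
  parent <- seq_len(id)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  for (i in seq_len(nr - 1L)) {
    a <- runs[[i]]; b <- runs[[i + 1L]]
    if (is.null(a) || is.null(b)) next
    for (ra in seq_len(nrow(a))) for (rb in seq_len(nrow(b)))
      # 8-connectivity: runs touch if column ranges overlap or are diagonal
      if (a[ra, 1L] <= b[rb, 2L] + 1L && b[rb, 1L] <= a[ra, 2L] + 1L)
        union(a[ra, 3L], b[rb, 3L])
  }
  roots <- vapply(seq_len(id), find, integer(1L))
  relabel <- integer(id)
  nxt <- 0L
  for (r in roots) if (relabel[r] == 0L) { nxt <- nxt + 1L; relabel[r] <- nxt }
  for (i in seq_len(nr)) {
    a <- runs[[i]]
    if (is.null(a)) next
    for (ra in seq_len(nrow(a)))
      lab[i, a[ra, 1L]:a[ra, 2L]] <- relabel[roots[a[ra, 3L]]]
  }
  lab
}

#' Read a region mask for a frame
#'
#' Accepts a single-page grayscale TIFF (nonzero pixels are members) or a
#' run-length JSON file with fields `shape` (`[n_alines, n_depth]`) and `runs`
#' (list of `[row, start, length]`, all 0-based, runs along depth).
#'
#' @param mask_path mask file (`.json` for run-length, TIFF otherwise).
#' @param frame the [polar_frame()] the mask annotates (dimension check).
#' @return a [region_mask()].
#' @export
read_mask <- function(mask_path, frame) {
  if (grepl("\\.json$", mask_path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(mask_path, simplifyVector = TRUE)
    if (is.null(j$shape)) abort_format("mask JSON missing 'shape'")
    member <- matrix(FALSE, j$shape[1L], j$shape[2L])
    runs <- j$runs
    if (length(runs)) {
      if (!is.matrix(runs)) runs <- do.call(rbind, runs)
      for (r in seq_len(nrow(runs)))
        member[runs[r, 1L] + 1L, runs[r, 2L] + 1L:runs[r, 3L]] <- TRUE
    }
  } else {
    pages <- read_tiff_stack(mask_path)
    if (length(pages) != 1L) abort_format("mask must be a single-page image: ", mask_path)
    member <- pages[[1L]] != 0
  }
  if (!all(dim(member) == dim(frame)))
    abort_format("mask dimensions (", paste(dim(member), collapse = "x"),
                 ") do not match frame (", paste(dim(frame), collapse = "x"), ")")
  region_mask(member, frame_id = frame$frame_id)
}

#' Write a region mask as run-length JSON
#'
#' @param mask a [region_mask()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  runs <- list()
  for (i in seq_len(nrow(mask$member))) {
    d <- diff(c(FALSE, mask$member[i, ], FALSE))
    starts <- which(d == 1L); ends <- which(d == -1L) - 1L
    for (k in seq_along(starts))
      runs[[length(runs) + 1L]] <- c(i - 1L, starts[k] - 1L, ends[k] - starts[k] + 1L)
  }
  jsonlite::write_json(list(shape = dim(mask$member), order = "row-major",
                            runs = runs, frame_id = mask$frame_id),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Validate a table of observer TAS readings
#'
#' @param df data.frame with columns `patient_id`, `observer_id`, `session`
#'   (1 or 2) and `tas` (integer 1-6).
#' @return the validated data.frame (class `observer_readings` prepended).
#' @export
observer_readings <- function(df) {
  need <- c("patient_id", "observer_id", "session", "tas")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort_validation("readings table missing columns: ",
                                     paste(miss, collapse = ", "))
  if (!all(df$session %in% c(1L, 2L))) abort_validation("session must be 1 or 2")
  if (!all(df$tas %in% 1:6)) abort_validation("tas must be an integer in 1..6")
  class(df) <- c("observer_readings", class(df))
  df
}

#' Write a statistics table as CSV (lossless numeric round-trip)
#'
#' Numeric columns are serialised with 17 significant digits so that
#' write-then-read reproduces doubles bit-identically.
#'
#' @param records data.frame sharing one schema (may have zero rows).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_statistics_table <- function(records, path) {
  if (!is.data.frame(records)) abort_validation("records must be a data.frame")
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = TRUE),
           error = function(e) stop(errorCondition(
             paste0("cannot write ", path, ": ", conditionMessage(e)),
             class = c("octhrombus_io_error", "error"))))
  invisible(path)
}

#' Read a statistics table written by [write_statistics_table()]
#'
#' @param path CSV path.
#' @return data.frame with numeric columns restored.
#' @export
read_statistics_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.character(df[[j]])) {
      suppressWarnings(num <- as.numeric(df[[j]]))
      blank <- df[[j]] == "" | df[[j]] == "NA"
      if (all(is.finite(num) | blank | is.na(df[[j]]))) {
        num[blank] <- NA_real_
        df[[j]] <- num
      }
    }
  }
  df
}
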