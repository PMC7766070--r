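#' Multichannel EHG record
#'
#' Container for a multichannel electrohysterogram (EHG) record: the three
#' bipolar abdominal signals S1, S2, S3 (optionally a measured S4 and the
#' tocogram), a sampling frequency, a group label and interval annotations.
#' All channels must share the same length and sampling frequency.
#'
#' @param record_id character scalar identifying the record.
#' @param fs sampling frequency in Hz (20 Hz for the term/preterm dataset).
#' @param signals named list of equal-length numeric vectors. Channel names
#'   `S1`, `S2`, `S3` are expected for analysis; `S4_measured`, `TOCO` and the
#'   unipolar potentials `E1`..`E4` (synthetic records) are carried through.
#' @param group one of `"preterm"`, `"term"`, `"nonpregnant"`, `"synthetic"`.
#' @param gestation_weeks_at_recording,gestation_weeks_at_delivery optional
#'   gestational ages in weeks.
#' @param annotations data frame of annotated intervals as produced by
#'   [annotated_intervals()].
#' @param truth optional list of ground-truth metadata (synthetic records).
#' @return An object of class `ehg_record`.
#' @seealso [read_record()], [write_record()], [annotated_intervals()]
#' @export
ehg_record <- function(record_id, fs, signals,
                       group = c("synthetic", "preterm", "term", "nonpregnant"),
                       gestation_weeks_at_recording = NA_real_,
                       gestation_weeks_at_delivery = NA_real_,
                       annotations = annotated_intervals(),
                       truth = NULL) {
  group <- match.arg(group)
  assert_that(is.character(record_id) && length(record_id) == 1L,
              "record_id must be a character scalar")
  assert_that(is.numeric(fs) && length(fs) == 1L && fs > 0, "fs must be > 0")
  assert_that(is.list(signals) && length(signals) >= 1L &&
                !is.null(names(signals)) && all(nzchar(names(signals))),
              "signals must be a named list of numeric vectors")
  lens <- vapply(signals, length, integer(1))
  assert_that(length(unique(lens)) == 1L,
              "all channels must have the same length", class = "ehg_structural_error")
  assert_that(lens[[1]] > 0, "record duration must be > 0")
  signals <- lapply(signals, as.numeric)
  rec <- structure(list(
    record_id = record_id, fs = fs, signals = signals, group = group,
    gestation_weeks_at_recording = gestation_weeks_at_recording,
    gestation_weeks_at_delivery = gestation_weeks_at_delivery,
    annotations = annotated_intervals(), truth = truth
  ), class = "ehg_record")
  set_annotations(rec, annotations)
}

#' Annotated intervals of a record
#'
#' Builds the canonical interval table: typed (`dummy` / `contraction`)
#' half-open sample spans `[start, end)` in 0-based sample indices.
#'
#' @param kind character vector, each `"dummy"` or `"contraction"`.
#' @param start,end integer sample indices, `0 <= start < end`.
#' @return data frame with columns `kind`, `start`, `end`.
#' @export
annotated_intervals <- function(kind = character(), start = integer(), end = integer()) {
  assert_that(length(kind) == length(start) && length(start) == length(end),
              "kind, start, end must have equal length")
  assert_that(all(kind %in% c("dummy", "contraction")),
              "interval kind must be 'dummy' or 'contraction'")
  start <- as.integer(start); end <- as.integer(end)
  assert_that(all(start >= 0L) && all(end > start),
              "intervals require 0 <= start < end")
  data.frame(kind = as.character(kind), start = start, end = end,
             stringsAsFactors = FALSE)
}

set_annotations <- function(record, intervals) {
  n <- record_length(record)
  intervals <- annotated_intervals(intervals$kind, intervals$start, intervals$end)
  assert_that(all(intervals$end <= n),
              "annotated intervals must lie within record bounds",
              class = "ehg_structural_error")
  record$annotations <- intervals
  record
}

record_length <- function(record) length(record$signals[[1]])
record_duration <- function(record) record_length(record) / record$fs

#' @export
print.ehg_record <- function(x, ...) {
  cat(sprintf("<ehg_record> %s (%s)\n", x$record_id, x$group))
  cat(sprintf("  fs = %g Hz, duration = %.1f s, channels: %s\n",
              x$fs, record_duration(x), paste(names(x$signals), collapse = ", ")))
  if (nrow(x$annotations))
    cat(sprintf("  annotations: %s\n",
                paste(sprintf("%d %s", table(x$annotations$kind),
                              names(table(x$annotations$kind))), collapse = ", ")))
  invisible(x)
}

#' Infer the study group from a record name
#'
#' Record-name prefixes of the term/preterm dataset encode the group:
#' `tpehgt_p*` preterm, `tpehgt_t*` term, `tpehgt_n*` non-pregnant. Anything
#' else is treated as synthetic.
#'
#' @param record_id record name.
#' @return group label string.
#' @export
infer_group <- function(record_id) {
  if (grepl("^tpehgt_p", record_id)) "preterm"
  else if (grepl("^tpehgt_t", record_id)) "term"
  else if (grepl("^tpehgt_n", record_id)) "nonpregnant"
  else "synthetic"
}

## ---- WFDB header + signal files (format 16) --------------------------------

#' Read a WFDB record
#'
#' Reads a WFDB header (`.hea`) and its companion 16-bit signal file into an
#' [ehg_record()]. Physical values are reconstructed as
#' `(adc - baseline) / gain`. Only single-segment, format-16 records are
#' supported, which covers the term/preterm EHG dataset.
#'
#' @param path path to the `.hea` file (the extension may be omitted).
#' @param group optional group override; by default inferred from the record
#'   name via [infer_group()].
#' @param annotations optional path of an annotation file to attach, read with
#'   [read_annotations()].
#' @param mapping annotation symbol table, see [annotation_mapping()].
#' @return An `ehg_record`.
#' @export
read_record <- function(path, group = NULL, annotations = NULL,
                        mapping = annotation_mapping()) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  assert_that(file.exists(hea), "missing WFDB header: ", hea,
              class = "ehg_format_error")
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  assert_that(length(lines) >= 2L, "corrupt WFDB header: ", hea,
              class = "ehg_format_error")
  head_f <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  assert_that(length(head_f) >= 4L, "corrupt WFDB header line: ", lines[[1]],
              class = "ehg_format_error")
  rec_name <- sub("/.*$", "", head_f[[1]])
  nsig <- as.integer(head_f[[2]])
  fs <- as.numeric(sub("/.*$", "", head_f[[3]]))
  nsamp <- as.integer(head_f[[4]])
  assert_that(is.finite(nsig) && nsig >= 1L, "bad signal count in header",
              class = "ehg_format_error")
  sig_lines <- lines[2:(1 + nsig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    assert_that(length(f) >= 2L, "corrupt signal line: ", ln,
                class = "ehg_format_error")
    gain_spec <- if (length(f) >= 3L) f[[3]] else "200"
    gain <- as.numeric(sub("^([-0-9.eE+]+).*$", "\\1", gain_spec))
    baseline <- if (grepl("\\(", gain_spec))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec)) else 0
    units <- if (grepl("/", gain_spec)) sub("^.*/", "", gain_spec) else "uV"
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else NA_character_
    list(file = f[[1]], format = as.integer(sub(":.*|\\+.*", "", f[[2]])),
         gain = if (is.na(gain) || gain == 0) 200 else gain,
         baseline = baseline, units = units, desc = desc)
  }
  sigs <- lapply(sig_lines, parse_sig)
  fmts <- vapply(sigs, `[[`, integer(1), "format")
  assert_that(all(fmts == 16L), "only WFDB signal format 16 is supported",
              class = "ehg_format_error")
  dat_file <- unique(vapply(sigs, `[[`, character(1), "file"))
  assert_that(length(dat_file) == 1L, "multi-file WFDB records are not supported",
              class = "ehg_format_error")
  dat_path <- file.path(dirname(hea), dat_file)
  assert_that(file.exists(dat_path), "missing WFDB signal file: ", dat_path,
              class = "ehg_format_error")
  raw_n <- file.info(dat_path)$size / 2L
  adc <- readBin(dat_path, what = "integer", n = raw_n, size = 2L,
                 endian = "little", signed = TRUE)
  if (is.na(nsamp) || nsamp == 0L) nsamp <- length(adc) %/% nsig
  assert_that(length(adc) >= nsig * nsamp, "truncated WFDB signal file",
              class = "ehg_format_error")
  adc <- matrix(adc[seq_len(nsig * nsamp)], nrow = nsig)
  ch_names <- vapply(seq_along(sigs), function(i)
    if (is.na(sigs[[i]]$desc)) paste0("ch", i) else sigs[[i]]$desc, character(1))
  signals <- stats::setNames(lapply(seq_len(nsig), function(i)
    (adc[i, ] - sigs[[i]]$baseline) / sigs[[i]]$gain), ch_names)
  rec <- ehg_record(rec_name, fs, signals, group = group %||% infer_group(rec_name))
  if (!is.null(annotations))
    rec <- set_annotations(rec, read_annotations(annotations, rec, mapping = mapping))
  sidecar <- file.path(dirname(hea), paste0(rec_name, ".truth.json"))
  if (file.exists(sidecar)) rec$truth <- jsonlite::fromJSON(sidecar, simplifyDataFrame = FALSE)
  rec
}

#' Write a WFDB record
#'
#' Writes an [ehg_record()] as a WFDB header plus 16-bit signal file.
#' Samples are quantized as `round(x * gain) + baseline`; a record whose
#' samples are integer multiples of `1/gain` round-trips bit-exactly through
#' [read_record()]. Synthetic ground truth (`record$truth`), when present, is
#' written to a JSON sidecar `<record>.truth.json`.
#'
#' @param record an `ehg_record`.
#' @param dir output directory (created if needed).
#' @param gain ADC gain in units per physical unit (default 200).
#' @return Invisibly, the path of the written header file.
#' @export
write_record <- function(record, dir, gain = 200) {
  assert_that(inherits(record, "ehg_record"), "record must be an ehg_record")
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stop_ehg("cannot create directory: ", dir, class = "ehg_io_error")
  long <- names(record$signals)[nchar(names(record$signals)) > 50L]
  assert_that(length(long) == 0L,
              "channel name exceeds the 50-character header limit: ",
              paste(long, collapse = ", "))
  nsig <- length(record$signals)
  n <- record_length(record)
  adc <- vapply(record$signals, function(x) as.integer(round(x * gain)), integer(n))
  assert_that(all(abs(adc) <= 32767L),
              "signal amplitude exceeds the 16-bit range at gain ", gain,
              class = "ehg_io_error")
  dat <- paste0(record$record_id, ".dat")
  hea <- file.path(dir, paste0(record$record_id, ".hea"))
  con <- file(hea, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("%s %d %g %d", record$record_id, nsig, record$fs, n), con)
  for (i in seq_len(nsig)) {
    writeLines(sprintf("%s 16 %g(0)/uV 16 0 %d 0 0 %s",
                       dat, gain, adc[1L, i], names(record$signals)[i]), con)
  }
  writeLines(paste0("# group: ", record$group), con)
  writeBin(as.integer(t(adc)), file.path(dir, dat), size = 2L, endian = "little")
  if (!is.null(record$truth))
    jsonlite::write_json(record$truth, file.path(dir, paste0(record$record_id, ".truth.json")),
                         auto_unbox = TRUE, digits = NA)
  invisible(hea)
}

## ---- WFDB (MIT-format) annotations -----------------------------------------

#' Annotation symbol table
#'
#' Mapping from the aux strings of WFDB NOTE annotations to typed interval
#' boundaries. The dataset's own documentation defines the symbol scheme, so
#' the table is configurable rather than hard-coded; the default follows the
#' `(c`/`c)` begin/end convention for contraction and `(d`/`d)` for dummy
#' intervals.
#'
#' @param aux character vector of aux strings.
#' @param kind interval kind per aux string.
#' @param role `"begin"` or `"end"` per aux string.
#' @return data frame with columns `aux`, `kind`, `role`.
#' @export
annotation_mapping <- function(aux = c("(c", "c)", "(d", "d)"),
                               kind = c("contraction", "contraction", "dummy", "dummy"),
                               role = c("begin", "end", "begin", "end")) {
  assert_that(length(aux) == length(kind) && length(kind) == length(role),
              "aux, kind, role must have equal length")
  data.frame(aux = aux, kind = kind, role = role, stringsAsFactors = FALSE)
}

ANN_NOTE <- 22L
ANN_SKIP <- 59L
ANN_AUX <- 63L

#' Read WFDB annotations into typed intervals
#'
#' Reads an MIT-format annotation file and pairs its begin/end marks into
#' half-open `[start, end)` sample intervals using the symbol table. Unpaired
#' marks raise a parse error naming the offending annotations.
#'
#' @param path annotation file.
#' @param record the `ehg_record` the annotations belong to (for bounds checks).
#' @param mapping symbol table from [annotation_mapping()].
#' @return data frame of intervals as in [annotated_intervals()].
#' @export
read_annotations <- function(path, record, mapping = annotation_mapping()) {
  assert_that(file.exists(path), "missing annotation file: ", path,
              class = "ehg_format_error")
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  marks <- parse_mit_annotations(raw)
  marks <- marks[!is.na(marks$aux), , drop = FALSE]
  if (nrow(marks) == 0L) return(annotated_intervals())
  m <- merge(marks, mapping, by = "aux", sort = FALSE)
  unknown <- setdiff(marks$aux, mapping$aux)
  assert_that(length(unknown) == 0L,
              "unmapped annotation aux strings: ", paste(unknown, collapse = ", "),
              class = "ehg_parse_error")
  m <- m[order(m$time), ]
  out <- list()
  for (kd in unique(m$kind)) {
    mk <- m[m$kind == kd, ]
    open <- NULL
    for (i in seq_len(nrow(mk))) {
      if (mk$role[i] == "begin") {
        assert_that(is.null(open), "unpaired begin mark '", mk$aux[i],
                    "' at sample ", mk$time[i], class = "ehg_parse_error")
        open <- mk$time[i]
      } else {
        assert_that(!is.null(open), "unpaired end mark '", mk$aux[i],
                    "' at sample ", mk$time[i], class = "ehg_parse_error")
        out[[length(out) + 1L]] <- data.frame(kind = kd, start = open,
                                              end = mk$time[i])
        open <- NULL
      }
    }
    assert_that(is.null(open), "unpaired begin mark for '", kd,
                "' at sample ", open %||% NA, class = "ehg_parse_error")
  }
  iv <- do.call(rbind, out)
  iv <- iv[order(iv$start), ]
  iv <- annotated_intervals(iv$kind, iv$start, iv$end)
  assert_that(all(iv$end <= record_length(record)),
              "annotation beyond record bounds", class = "ehg_parse_error")
  iv
}

# Decode the MIT annotation byte stream: little-endian 16-bit words with a
# 6-bit type code and 10-bit payload; SKIP carries a 32-bit time offset in the
# following two words, AUX a string of payload-many bytes (padded to even).
parse_mit_annotations <- function(raw) {
  words <- function(i) {
    as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  }
  i <- 1L; t_acc <- 0; pending_skip <- 0
  times <- integer(); auxs <- character(); codes <- integer()
  nb <- length(raw)
  while (i + 1L <= nb) {
    w <- words(i); i <- i + 2L
    code <- w %/% 1024L; payload <- w %% 1024L
    if (w == 0L) break
    if (code == ANN_SKIP) {
      assert_that(i + 3L <= nb, "truncated SKIP annotation", class = "ehg_parse_error")
      hi <- words(i); lo <- words(i + 2L); i <- i + 4L
      pending_skip <- pending_skip + hi * 65536 + lo
    } else if (code == ANN_AUX) {
      assert_that(length(times) > 0L, "AUX before any annotation",
                  class = "ehg_parse_error")
      nbytes <- payload
      aux <- rawToChar(raw[i:(i + nbytes - 1L)])
      i <- i + nbytes + (nbytes %% 2L)
      auxs[length(auxs)] <- aux
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM / SUB / CHN modifiers: parsed and ignored
    } else {
      t_acc <- t_acc + pending_skip + payload
      pending_skip <- 0
      times <- c(times, as.integer(t_acc))
      codes <- c(codes, code)
      auxs <- c(auxs, NA_character_)
    }
  }
  data.frame(time = times, code = codes, aux = auxs, stringsAsFactors = FALSE)
}

#' Write typed intervals as WFDB annotations
#'
#' Serializes interval begin/end marks as MIT-format NOTE annotations with aux
#' strings taken from the symbol table. Inverse of [read_annotations()].
#'
#' @param intervals interval table, see [annotated_intervals()].
#' @param path output file.
#' @param mapping symbol table from [annotation_mapping()].
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(intervals, path, mapping = annotation_mapping()) {
  if (nrow(intervals) == 0L) {
    writeBin(as.raw(c(0L, 0L)), path)
    return(invisible(path))
  }
  marks <- rbind(
    data.frame(time = intervals$start, kind = intervals$kind, role = "begin"),
    data.frame(time = intervals$end, kind = intervals$kind, role = "end"))
  marks <- merge(marks, mapping, by = c("kind", "role"), sort = FALSE)
  marks <- marks[order(marks$time), ]
  out <- raw()
  word <- function(code, payload) {
    w <- code * 1024L + payload
    as.raw(c(w %% 256L, w %/% 256L))
  }
  t_prev <- 0L
  for (i in seq_len(nrow(marks))) {
    dt <- marks$time[i] - t_prev
    t_prev <- marks$time[i]
    if (dt > 1023L) {
      out <- c(out, word(ANN_SKIP, 0L),
               as.raw(c((dt %/% 65536L) %% 256L, dt %/% 16777216L,
                        dt %% 256L, (dt %/% 256L) %% 256L)))
      dt <- 0L
    }
    out <- c(out, word(ANN_NOTE, dt))
    aux <- marks$aux[i]
    nbytes <- nchar(aux)
    out <- c(out, word(ANN_AUX, nbytes), charToRaw(aux))
    if (nbytes %% 2L) out <- c(out, as.raw(0L))
  }
  out <- c(out, as.raw(c(0L, 0L)))
  writeBin(out, path)
  invisible(path)
}

#' Census of a term/preterm EHG dataset directory
#'
#' Parses every record of a locally available copy of the public term/preterm
#' EHG dataset with tocogram and tallies records by group and annotated
#' intervals by (group, kind). The dataset is distributed by PhysioNet and must
#' be downloaded once; point `dir` (or `options(ehgcv.dataset_dir=)` /
#' `EHGCV_TPEHGT_DIR`) at the directory holding the `tpehgt_*` files.
#'
#' @param dir dataset directory, defaulting to [ehg_dataset_dir()].
#' @param mapping annotation symbol table.
#' @return list with `records` (counts by group) and `intervals` (counts by
#'   group and kind).
#' @export
tpehgt_census <- function(dir = ehg_dataset_dir(), mapping = annotation_mapping()) {
  assert_that(dir.exists(dir), "dataset directory not found: ", dir,
              class = "ehg_io_error")
  heas <- list.files(dir, pattern = "^tpehgt_.*\\.hea$", full.names = TRUE)
  assert_that(length(heas) > 0L, "no tpehgt_* records under ", dir,
              class = "ehg_io_error")
  groups <- character(); ivs <- list()
  for (h in heas) {
    base <- sub("\\.hea$", "", h)
    atr <- paste0(base, ".atr")
    rec <- read_record(h, annotations = if (file.exists(atr)) atr else NULL,
                       mapping = mapping)
    groups <- c(groups, rec$group)
    if (nrow(rec$annotations))
      ivs[[length(ivs) + 1L]] <- cbind(rec$annotations, group = rec$group)
  }
  iv <- if (length(ivs)) do.call(rbind, ivs) else NULL
  list(records = table(groups),
       intervals = if (is.null(iv)) table(character(), character())
                   else table(iv$group, iv$kind))
}

#' @rdname tpehgt_census
#' @export
ehg_dataset_dir <- function() {
  getOption("ehgcv.dataset_dir",
            Sys.getenv("EHGCV_TPEHGT_DIR", file.path(path.expand("~"), "tpehgt")))
}
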