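# Electrode montages: named partitions of channel labels into brain areas.

#' Reference 32-channel montage channel order
#'
#' The canonical channel ordering of the 32-electrode 10-20 montage used by
#' the DEAP recordings. All loaders permute input channels to this order so
#' that downstream matrix indices are stable.
#'
#' @return Character vector of 32 channel labels.
#' @export
#' @examples
#' deap_channels()
deap_channels <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
    "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
    "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
    "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
}

#' Construct an electrode montage
#'
#' A montage assigns channel labels to named brain areas. Labels listed in
#' `unassigned` are declared as intentionally outside every area (for the
#' reference montage these are the four midline electrodes, which belong to
#' neither hemisphere); any other label that is neither assigned nor declared
#' fails validation.
#'
#' @param areas Named list; each element is a character vector of channel
#'   labels belonging to that area, in area order.
#' @param unassigned Character vector of labels deliberately left out of all
#'   areas.
#' @param name Identifier for the montage.
#' @return An object of class `eeg_montage`.
#' @export
montage <- function(areas, unassigned = character(), name = "custom") {
  if (!is.list(areas) || is.null(names(areas)) || any(names(areas) == "")) {
    stopf("`areas` must be a named list of channel-label vectors")
  }
  areas <- lapply(areas, as.character)
  structure(
    list(name = name,
         area_names = names(areas),
         areas = areas,
         unassigned = as.character(unassigned)),
    class = "eeg_montage"
  )
}

#' Six-area reference montage for the 32-channel layout
#'
#' Splits each hemisphere into three regions — frontal; central/temporal;
#' parietal/occipital — yielding six areas of sizes 5, 5, 4, 4, 5, 5. The
#' midline electrodes (Fz, Cz, Pz, Oz) lie on neither hemisphere and are
#' declared unassigned; they take part in 32-channel analyses but not in
#' area averaging.
#'
#' @return An `eeg_montage` with areas `Area1` ... `Area6`.
#' @export
#' @examples
#' m <- deap_montage()
#' lengths(m$areas)
deap_montage <- function() {
  montage(
    areas = list(
      Area1 = c("Fp1", "AF3", "F3", "FC5", "F7"),
      Area2 = c("Fp2", "AF4", "F4", "FC6", "F8"),
      Area3 = c("FC1", "CP1", "C3", "T7"),
      Area4 = c("FC2", "CP2", "C4", "T8"),
      Area5 = c("CP5", "P3", "PO3", "O1", "P7"),
      Area6 = c("CP6", "P4", "PO4", "O2", "P8")
    ),
    unassigned = c("Fz", "Cz", "Pz", "Oz"),
    name = "deap32"
  )
}

#' Validate a channel set against a montage
#'
#' Report-style check of the partition invariant: every montage label must be
#' present in `channel_names` exactly once, no label may belong to two areas,
#' and every channel must either belong to one area or be declared
#' unassigned.
#'
#' @param channel_names Character vector of available channel labels.
#' @param montage An `eeg_montage`.
#' @return A `montage_report` list with elements `ok`, `missing` (montage
#'   labels absent from the channels), `duplicates` (labels in more than one
#'   area), `undeclared` (channels in no area and not declared unassigned),
#'   `unassigned` (declared midline-style labels present) and `area_sizes`.
#' @export
#' @examples
#' validate_montage(deap_channels(), deap_montage())$area_sizes
validate_montage <- function(channel_names, montage) {
  stopifnot(inherits(montage, "eeg_montage"))
  assigned <- unlist(montage$areas, use.names = FALSE)
  duplicates <- unique(assigned[duplicated(assigned)])
  wanted <- unique(c(assigned, montage$unassigned))
  missing <- setdiff(wanted, channel_names)
  undeclared <- setdiff(channel_names, wanted)
  report <- structure(
    list(
      ok = length(duplicates) == 0L && length(missing) == 0L &&
        length(undeclared) == 0L,
      missing = missing,
      duplicates = duplicates,
      undeclared = undeclared,
      unassigned = intersect(montage$unassigned, channel_names),
      area_sizes = lengths(montage$areas)
    ),
    class = "montage_report"
  )
  report
}

#' @export
print.montage_report <- function(x, ...) {
  cat("Montage validation:", if (x$ok) "PASS" else "FAIL", "\n")
  cat("  area sizes:", paste(x$area_sizes, collapse = ", "), "\n")
  if (length(x$unassigned)) {
    cat("  declared unassigned:", paste(x$unassigned, collapse = ", "), "\n")
  }
  if (length(x$missing)) {
    cat("  missing channels:", paste(x$missing, collapse = ", "), "\n")
  }
  if (length(x$duplicates)) {
    cat("  duplicated labels:", paste(x$duplicates, collapse = ", "), "\n")
  }
  if (length(x$undeclared)) {
    cat("  undeclared channels:", paste(x$undeclared, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage '%s'> %d areas, %d assigned channels\n",
              x$name, length(x$areas), length(unlist(x$areas))))
  for (a in x$area_names) {
    cat(" ", a, ":", paste(x$areas[[a]], collapse = ", "), "\n")
  }
  if (length(x$unassigned)) {
    cat("  unassigned:", paste(x$unassigned, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a montage from a plain-text config
#'
#' Format: one line per area, `<AreaName>: <label> <label> ...`; an optional
#' line `unassigned: <label> ...` declares labels outside every area.
#'
#' @param path Path to the montage file.
#' @return An `eeg_montage`.
#' @export
read_montage <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  areas <- list()
  unassigned <- character()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stopf("malformed montage line: '%s'", ln)
    key <- trimws(parts[1])
    labels <- strsplit(trimws(parts[2]), "[,[:space:]]+")[[1]]
    labels <- labels[nzchar(labels)]
    if (identical(tolower(key), "unassigned")) {
      unassigned <- labels
    } else {
      areas[[key]] <- labels
    }
  }
  montage(areas, unassigned = unassigned,
          name = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a montage to a plain-text config
#'
#' @param montage An `eeg_montage`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_montage <- function(montage, path) {
  stopifnot(inherits(montage, "eeg_montage"))
  lines <- vapply(montage$area_names, function(a) {
    paste0(a, ": ", paste(montage$areas[[a]], collapse = " "))
  }, character(1))
  if (length(montage$unassigned)) {
    lines <- c(lines,
               paste0("unassigned: ", paste(montage$unassigned, collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}
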