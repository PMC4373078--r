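#' The canonical shell-scoring character set
#'
#' Fifteen categorical shell characters used to score *Melanoides* specimens:
#' background colour (IN, TI, HE), colour patterning (DO, SP, SO, HO),
#' columellar band (SH, SC), general shape (CO, RO) and sculpture
#' (GR, CD, RI, RD). Three characters are conditionally inapplicable:
#' patterning traits SP/SO/HO only exist when some patterning is present
#' (DO > 0), band size SC only when a band is present (SH > 1), and rib
#' depth RD only when ribs are present (RI > 0).
#'
#' @return A tibble with one row per character: `code`, `description`,
#'   `min_state`, `max_state`, a list-column `states` of allowed integer
#'   states, and `na_code`/`na_states` describing when the character is
#'   inapplicable (`na_code` is the controlling character; the trait is
#'   inapplicable when the controller takes a state in `na_states`).
#' @examples
#' canonical_character_set()
#' @export
canonical_character_set <- function() {
  def <- tibble::tribble(
    ~code, ~description,                                            ~min_state, ~max_state, ~na_code, ~na_states,
    "IN",  "intensity of the shell background color",               1L, 4L, NA_character_, list(NULL),
    "TI",  "background tint of the shell",                          1L, 5L, NA_character_, list(NULL),
    "HE",  "heterogeneity of the background color along the whorl", 0L, 1L, NA_character_, list(NULL),
    "DO",  "overall density of color patterning",                   0L, 2L, NA_character_, list(NULL),
    "SP",  "type of patterning (spots vs. flames)",                 0L, 3L, "DO", list(0L),
    "SO",  "size of the individual spots/flames",                   1L, 3L, "DO", list(0L),
    "HO",  "heterogeneity of patterning along the whorl",           1L, 3L, "DO", list(0L),
    "SH",  "presence and sharpness of the columellar band",         1L, 3L, NA_character_, list(NULL),
    "SC",  "size of the columellar band, when present",             1L, 3L, "SH", list(1L),
    "CO",  "conicity of the shell",                                 1L, 3L, NA_character_, list(NULL),
    "RO",  "roundness of the body whorl",                           1L, 3L, NA_character_, list(NULL),
    "GR",  "spiral cords/grooves",                                  0L, 3L, NA_character_, list(NULL),
    "CD",  "subsutural spiral cord",                                0L, 3L, NA_character_, list(NULL),
    "RI",  "density and width of axial ribs",                       0L, 3L, NA_character_, list(NULL),
    "RD",  "depth of axial ribs, when present",                     1L, 3L, "RI", list(0L)
  )
  def$na_states <- lapply(def$na_states, function(s) {
    if (is.null(s)) integer(0) else as.integer(unlist(s))
  })
  def$states <- purrr::map2(def$min_state, def$max_state, seq.int)
  def
}

# metadata columns a character table may carry in addition to the scores
.meta_cols <- c("specimen_id", "population_code", "species", "group",
                "clade", "unbleached")

parse_cell <- function(cell) {
  # "3" -> 3L ; "2, 3" -> c(2L, 3L) ; "na"/"" -> NULL (missing)
  cell <- tolower(trimws(cell))
  if (is.na(cell) || cell %in% c("na", "")) return(NULL)
  parts <- suppressWarnings(as.integer(trimws(strsplit(cell, ",")[[1]])))
  if (anyNA(parts)) return(NA_integer_)  # sentinel: unparseable
  sort(unique(parts))
}

#' Read and validate a specimen-by-character score table
#'
#' Reads a CSV with one row per specimen, metadata columns (`specimen_id`,
#' `population_code`, `group`, optionally `species`, `clade`, `unbleached`)
#' and one column per character code. Cells contain a single state (`"3"`),
#' a two-state borderline score (`"2, 3"`, recorded when independent
#' examiners coded the trait differently), or `"na"` where the trait is
#' inapplicable. The table is validated against the character definitions:
#' states must lie in each character's allowed range, borderline cells must
#' contain exactly two distinct states, and `na` is accepted only where the
#' character's inapplicability rule permits it (or on rows flagged
#' `unbleached`, whose organic coating hides colour traits).
#'
#' @param path Path to the CSV file.
#' @param definitions Character definitions, by default
#'   [canonical_character_set()].
#' @return A `character_matrix`: a tibble with the metadata columns and one
#'   character column per code, cells normalized to `"2"`/`"2,3"`/`NA`;
#'   the definitions travel along as an attribute.
#' @seealso [collapse_multistate()], [melanoides_shell_scores()]
#' @export
read_character_table <- function(path, definitions = canonical_character_set()) {
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  na.strings = character(0))
  as_character_matrix(raw, definitions = definitions)
}

#' Build a validated character matrix from a data frame
#'
#' @param x A data frame shaped like the CSV accepted by
#'   [read_character_table()].
#' @inheritParams read_character_table
#' @return A validated `character_matrix` tibble.
#' @export
as_character_matrix <- function(x, definitions = canonical_character_set()) {
  x <- tibble::as_tibble(x)
  if (!"specimen_id" %in% names(x)) {
    abort("character table must have a `specimen_id` column")
  }
  score_cols <- setdiff(names(x), .meta_cols)
  unknown <- setdiff(score_cols, definitions$code)
  if (length(unknown) > 0) {
    abort(paste0("unknown character code(s): ", paste(unknown, collapse = ", ")))
  }
  missing_chars <- setdiff(definitions$code, score_cols)
  if (length(missing_chars) > 0) {
    abort(paste0("character column(s) missing: ",
                 paste(missing_chars, collapse = ", ")))
  }
  if (anyDuplicated(x$specimen_id)) {
    abort(paste0("duplicate specimen_id: ",
                 paste(unique(x$specimen_id[duplicated(x$specimen_id)]),
                       collapse = ", ")))
  }
  if ("unbleached" %in% names(x)) {
    x$unbleached <- as.logical(x$unbleached)
  } else {
    x$unbleached <- FALSE
  }
  if (!"group" %in% names(x)) x$group <- "unknown"
  if (!"population_code" %in% names(x)) x$population_code <- x$specimen_id
  bad_group <- setdiff(unique(x$group), c("native", "invasive", "unknown"))
  if (length(bad_group) > 0) {
    abort(paste0("group must be native/invasive/unknown; found: ",
                 paste(bad_group, collapse = ", ")))
  }

  # normalize and validate every cell
  problems <- character(0)
  parsed <- list()
  for (code in definitions$code) {
    col <- as.character(x[[code]])
    cells <- lapply(col, parse_cell)
    def <- definitions[definitions$code == code, ]
    for (i in seq_along(cells)) {
      cell <- cells[[i]]
      where <- sprintf("specimen '%s', character %s", x$specimen_id[i], code)
      if (is.null(cell)) next
      if (anyNA(cell)) {
        problems <- c(problems, paste0("unparseable cell at ", where))
      } else if (!all(cell %in% def$states[[1]])) {
        problems <- c(problems,
                      sprintf("state(s) %s outside allowed range %d..%d at %s",
                              paste(setdiff(cell, def$states[[1]]), collapse = ","),
                              def$min_state, def$max_state, where))
      } else if (length(cell) > 2) {
        problems <- c(problems,
                      paste0("more than two states in borderline cell at ", where))
      }
    }
    parsed[[code]] <- cells
  }
  # 'na' only where the inapplicability rule (or an unbleached flag) allows it
  for (code in definitions$code) {
    def <- definitions[definitions$code == code, ]
    ctrl <- def$na_code
    for (i in seq_len(nrow(x))) {
      if (!is.null(parsed[[code]][[i]])) next
      if (isTRUE(x$unbleached[i])) next
      ok <- FALSE
      if (!is.na(ctrl)) {
        ctrl_cell <- parsed[[ctrl]][[i]]
        ok <- !is.null(ctrl_cell) && !anyNA(ctrl_cell) &&
          all(ctrl_cell %in% def$na_states[[1]])
      }
      if (!ok) {
        problems <- c(problems,
                      sprintf("'na' not permitted at specimen '%s', character %s%s",
                              x$specimen_id[i], code,
                              if (is.na(ctrl)) " (character is always applicable)"
                              else sprintf(" (requires %s in {%s})", ctrl,
                                           paste(def$na_states[[1]], collapse = ","))))
      }
    }
  }
  if (length(problems) > 0) {
    abort(c("character table validation failed", problems))
  }
  for (code in definitions$code) {
    x[[code]] <- vapply(parsed[[code]], function(cell) {
      if (is.null(cell)) NA_character_ else paste(cell, collapse = ",")
    }, character(1))
  }
  x <- x[c(intersect(.meta_cols, names(x)), definitions$code)]
  attr(x, "definitions") <- definitions
  class(x) <- c("character_matrix", class(x))
  x
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("<character_matrix: %d specimens x %d characters>\n",
              nrow(x), nrow(character_definitions(x))))
  NextMethod()
}

#' Character definitions attached to a score table
#'
#' @param x A `character_matrix` or collapsed numeric score table.
#' @return The definitions tibble (see [canonical_character_set()]).
#' @export
character_definitions <- function(x) {
  def <- attr(x, "definitions")
  if (is.null(def)) canonical_character_set() else def
}

#' Collapse borderline two-state scores to arithmetic means
#'
#' Converts a validated character matrix to a numeric score matrix: a single
#' state maps to itself, a borderline two-state cell maps to the arithmetic
#' mean of its states (`"2,3"` becomes 2.5), and inapplicable cells become
#' `NA`. The operation is idempotent on single-state inputs and independent
#' of row order.
#'
#' @param x A `character_matrix` from [read_character_table()] or
#'   [as_character_matrix()].
#' @return A tibble with the same metadata columns and one numeric column per
#'   character (class `numeric_scores`); definitions travel as an attribute.
#' @examples
#' scores <- melanoides_shell_scores()
#' collapse_multistate(scores)
#' @export
collapse_multistate <- function(x) {
  def <- character_definitions(x)
  out <- tibble::as_tibble(as.data.frame(x)[intersect(.meta_cols, names(x))])
  for (code in def$code) {
    out[[code]] <- vapply(x[[code]], function(cell) {
      if (is.na(cell)) return(NA_real_)
      mean(as.numeric(strsplit(cell, ",")[[1]]))
    }, numeric(1), USE.NAMES = FALSE)
  }
  attr(out, "definitions") <- def
  class(out) <- c("numeric_scores", class(out))
  out
}

# numeric specimens x characters matrix (rownames = specimen_id)
score_matrix <- function(x) {
  def <- character_definitions(x)
  m <- as.matrix(as.data.frame(x)[def$code])
  rownames(m) <- x$specimen_id
  storage.mode(m) <- "double"
  m
}

#' The published *Melanoides* shell-score table
#'
#' The specimen-by-character score matrix of 49 *Melanoides* specimens
#' (invasive and native *M. tuberculata* morphs plus endemic Congolese
#' *M.* cf. *liebrechtsi* / *nsendweensis* comparison material) scored on
#' the 15 canonical shell characters. Rows flagged `unbleached` were scored
#' with their organic coating in place, so colour traits reflect field
#' appearance.
#'
#' @return A validated `character_matrix` tibble (49 specimens).
#' @examples
#' melanoides_shell_scores()
#' @export
melanoides_shell_scores <- function() {
  path <- system.file("extdata", "melanoides_shell_scores.csv",
                      package = "melinvade", mustWork = TRUE)
  read_character_table(path)
}
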