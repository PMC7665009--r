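# OTU x character presence/absence matrices ----------------------------------

#' Construct an OTU-by-character presence/absence matrix
#'
#' The analysis substrate: rows are operational taxonomic units (a species
#' considered at a given landmark of its normalized developmental time),
#' columns are binary characters (organs or structures), and cells record
#' presence (`1`), absence (`0`) or unavailable data (`?`, stored as `NA`).
#'
#' Row labels follow the grammar `Genus_species_P%`: species name tokens
#' joined by underscores with a final token giving the landmark as a
#' percentage of developmental time (the `%` sign is optional).
#'
#' @param states integer or character matrix with values 0/1/`NA` (or
#'   `"0"`/`"1"`/`"?"`); rownames are OTU labels.
#' @param characters optional data frame with columns `index` (1..K,
#'   contiguous) and `name`; defaults to unnamed characters.
#' @param validate if `TRUE` (default), fail on any structural issue.
#' @return an object of class `onto_matrix`.
#' @seealso [parse_matrix_text()], [validate_matrix()], [load_fixture_table1()]
#' @export
character_matrix <- function(states, characters = NULL, validate = TRUE) {
  if (is.character(states)) {
    lab <- rownames(states)
    states <- matrix(suppressWarnings(as.integer(ifelse(states == "?", NA, states))),
                     nrow = nrow(states), dimnames = list(lab, colnames(states)))
  }
  storage.mode(states) <- "integer"
  if (is.null(rownames(states))) {
    .stop("ontochron_label_error", "OTU row labels are required")
  }
  parsed <- parse_otu_labels(rownames(states))
  if (is.null(characters)) {
    characters <- data.frame(index = seq_len(ncol(states)),
                             name = paste0("C", seq_len(ncol(states))))
  }
  m <- structure(list(states = states,
                      species = parsed$species,
                      landmark = parsed$landmark,
                      characters = characters),
                 class = "onto_matrix")
  if (validate) {
    iss <- validate_matrix(m)
    if (nrow(iss)) {
      .stop(paste0("ontochron_", iss$type[1], "_error"),
            "invalid matrix: %s", paste(unique(iss$message), collapse = "; "))
    }
  }
  m
}

# split "Genus_species_P%" labels into species and numeric landmark
parse_otu_labels <- function(labels) {
  toks <- strsplit(labels, "_", fixed = TRUE)
  last <- vapply(toks, function(x) x[length(x)], "")
  species <- vapply(toks, function(x) paste(x[-length(x)], collapse = "_"), "")
  landmark <- suppressWarnings(as.numeric(sub("%$", "", last)))
  bad <- is.na(landmark) | species == ""
  if (any(bad)) {
    .stop("ontochron_label_error",
          "cannot parse OTU label(s): %s (expected Genus_species_P%%)",
          paste(labels[bad], collapse = ", "))
  }
  list(species = species, landmark = landmark)
}

#' @export
print.onto_matrix <- function(x, ...) {
  cat(sprintf("OTU x character matrix: %d OTUs x %d characters\n",
              nrow(x$states), ncol(x$states)))
  cat(sprintf("  species  : %s\n", paste(unique(x$species), collapse = ", ")))
  cat(sprintf("  landmarks: %s%%\n",
              paste(sort(unique(x$landmark)), collapse = ", ")))
  nmiss <- sum(is.na(x$states))
  if (nmiss) cat(sprintf("  missing cells: %d\n", nmiss))
  invisible(x)
}

#' @export
dim.onto_matrix <- function(x) dim(x$states)

#' OTU labels of a matrix
#' @param m an `onto_matrix`.
#' @return character vector of row labels.
#' @export
otu_labels <- function(m) rownames(m$states)

#' @export
as.data.frame.onto_matrix <- function(x, ...) {
  data.frame(otu = rownames(x$states), species = x$species,
              landmark = x$landmark, x$states, check.names = FALSE,
              row.names = NULL)
}

#' Parse the simple text dialect for character matrices
#'
#' One OTU per line: a label of the form `Genus_species_P%` followed by
#' whitespace and a contiguous state string over `0`, `1`, `?`.
#'
#' @param text a single string or a character vector of lines.
#' @param characters optional character definitions (see
#'   [character_matrix()]).
#' @return an `onto_matrix`.
#' @export
parse_matrix_text <- function(text, characters = NULL) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) .stop("ontochron_dimension_error", "no matrix rows found")
  parts <- regmatches(lines, regexec("^(\\S+)\\s+(\\S+)$", lines))
  bad <- lengths(parts) != 3
  if (any(bad)) {
    .stop("ontochron_parse_error", "malformed line(s): %s",
          paste(lines[bad], collapse = " | "))
  }
  labels <- vapply(parts, `[`, "", 2)
  rows <- vapply(parts, `[`, "", 3)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) {
    .stop("ontochron_dimension_error",
          "ragged rows: lengths %s", paste(unique(widths), collapse = ", "))
  }
  chars <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  illegal <- !(chars %in% c("0", "1", "?"))
  if (any(illegal)) {
    .stop("ontochron_state_error", "illegal state symbol(s): %s",
          paste(unique(chars[illegal]), collapse = ", "))
  }
  if (anyDuplicated(labels)) {
    .stop("ontochron_uniqueness_error", "duplicate OTU label(s): %s",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  rownames(chars) <- labels
  character_matrix(chars, characters = characters)
}

#' Validate an OTU-by-character matrix
#'
#' Reporting counterpart of the constructor checks: returns an empty data
#' frame when dimensions are consistent, labels parse and are unique, and
#' every cell is one of present/absent/unknown.
#'
#' @param m an `onto_matrix` (possibly built with `validate = FALSE`).
#' @return data frame with columns `type`, `row`, `column`, `message`;
#'   zero rows when the matrix is valid.
#' @export
validate_matrix <- function(m) {
  issues <- data.frame(type = character(), row = integer(),
                       column = integer(), message = character())
  add <- function(type, row, column, message) {
    rbind(issues, data.frame(type = type, row = row, column = column,
                             message = message))
  }
  s <- m$states
  if (length(m$species) != nrow(s) || length(m$landmark) != nrow(s)) {
    issues <- add("dimension", NA, NA, "species/landmark length != row count")
  }
  bad <- which(!(s %in% c(0L, 1L)) & !is.na(s), arr.ind = TRUE)
  for (i in seq_len(nrow(bad))) {
    issues <- add("state", bad[i, 1], bad[i, 2],
                  sprintf("illegal state %s", s[bad[i, 1], bad[i, 2]]))
  }
  key <- paste(m$species, m$landmark)
  dup <- which(duplicated(key))
  for (i in dup) {
    issues <- add("uniqueness", i, NA,
                  sprintf("duplicate OTU %s at %g%%", m$species[i], m$landmark[i]))
  }
  out <- which(m$landmark < 0 | m$landmark > 100)
  for (i in out) {
    issues <- add("landmark", i, NA,
                  sprintf("landmark %g outside [0, 100]", m$landmark[i]))
  }
  ch <- m$characters
  if (!identical(ch$index, seq_len(ncol(s))) || any(!nzchar(ch$name))) {
    issues <- add("characters", NA, NA,
                  "character indices not contiguous from 1 or names empty")
  }
  issues
}

#' Subset a matrix by OTU
#'
#' @param m an `onto_matrix`.
#' @param i logical or integer row index.
#' @return a new `onto_matrix` (matrices are value objects; the input is
#'   never modified).
#' @export
subset_otus <- function(m, i) {
  character_matrix(m$states[i, , drop = FALSE], characters = m$characters)
}

# NEXUS / text / CSV interchange ----------------------------------------------

#' Write a matrix as a NEXUS DATA block
#'
#' Standard interchange with parsimony software: `NTAX`/`NCHAR` dimensions,
#' `SYMBOLS="01"`, `MISSING=?`. Character names, when present, are written
#' as a `CHARLABELS` command.
#'
#' @param m an `onto_matrix`.
#' @param file optional path; when given the text is also written there.
#' @return the NEXUS text, invisibly when `file` is given.
#' @export
write_nexus <- function(m, file = NULL) {
  if (!nrow(m$states)) .stop("ontochron_dimension_error", "empty matrix")
  rows <- apply(m$states, 1, function(r) paste(ifelse(is.na(r), "?", r), collapse = ""))
  labs <- format(rownames(m$states))
  txt <- c("#NEXUS",
           "BEGIN DATA;",
           sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m$states), ncol(m$states)),
           "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
           if (!all(m$characters$name == paste0("C", m$characters$index)))
             c("  CHARLABELS",
               paste0("    ", paste(sprintf("'%s'", m$characters$name), collapse = " "), ";"),
               NULL),
           "  MATRIX",
           paste0("    ", labs, "  ", rows),
           "  ;",
           "END;")
  txt <- paste(txt, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Read a character matrix from NEXUS, simple text, or CSV
#'
#' Dispatches on content: text starting with `#NEXUS` goes through
#' [ape::read.nexus.data()]; a header line starting with `otu,` is read as
#' CSV; anything else is the simple one-row-per-OTU dialect of
#' [parse_matrix_text()].
#'
#' @param file path to the matrix file.
#' @param characters optional character definitions.
#' @return an `onto_matrix`.
#' @export
read_matrix <- function(file, characters = NULL) {
  lines <- readLines(file, warn = FALSE)
  first <- trimws(lines[nzchar(trimws(lines))][1])
  if (toupper(first) == "#NEXUS") {
    dat <- ape::read.nexus.data(file)
    chars <- do.call(rbind, dat)
    if (is.null(characters)) characters <- .read_charlabels(lines)
    return(character_matrix(chars, characters = characters))
  }
  if (grepl("^\"?otu\"?\\s*,", first, ignore.case = TRUE)) {
    df <- read.csv(file, check.names = FALSE)
    s <- as.matrix(df[, -1, drop = FALSE])
    rownames(s) <- df[[1]]
    return(character_matrix(s, characters = characters))
  }
  parse_matrix_text(lines, characters = characters)
}

# pull quoted names out of a CHARLABELS command, if any
.read_charlabels <- function(lines) {
  i <- grep("CHARLABELS", lines, ignore.case = TRUE)
  if (!length(i)) return(NULL)
  block <- paste(lines[i:length(lines)], collapse = " ")
  block <- sub(".*CHARLABELS", "", block, ignore.case = TRUE)
  block <- sub(";.*", "", block)
  nm <- regmatches(block, gregexpr("'[^']*'", block))[[1]]
  if (!length(nm)) return(NULL)
  data.frame(index = seq_along(nm), name = gsub("'", "", nm))
}

#' Export a matrix as CSV
#'
#' @param m an `onto_matrix`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_matrix_csv <- function(m, file) {
  s <- m$states
  df <- data.frame(otu = rownames(s), s, check.names = FALSE)
  colnames(df)[-1] <- m$characters$name
  write.csv(df, file, row.names = FALSE, na = "?")
  invisible(file)
}

#' Export a matrix in the simple text dialect
#'
#' @param m an `onto_matrix`.
#' @param file optional output path.
#' @return the text, invisibly when `file` is given.
#' @export
write_matrix_text <- function(m, file = NULL) {
  rows <- apply(m$states, 1, function(r) paste(ifelse(is.na(r), "?", r), collapse = ""))
  txt <- paste(rownames(m$states), rows)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

# bundled fixture --------------------------------------------------------------

#' The bundled four-species developmental matrix
#'
#' Loads the transcription-checked 32-OTU x 53-character matrix for
#' *Barbus barbus*, *Tinca tinca*, *Hucho hucho* and *Thymallus thymallus*
#' coded at landmarks 0, 5, 10, 20, 25, 50, 75 and 100 percent of
#' normalized developmental time, together with the 53 character
#' definitions (fecundation through full fin-ray counts).  One printed row
#' label lacks its `%` sign; the parser accepts both forms and the loaded
#' labels are as printed.
#'
#' @return an `onto_matrix` with 32 OTUs and 53 characters.
#' @export
load_fixture_table1 <- function() {
  dir <- system.file("extdata", package = "ontochron", mustWork = TRUE)
  chars <- read.delim(file.path(dir, "table2_characters.tsv"))
  parse_matrix_text(readLines(file.path(dir, "table1_matrix.txt")),
                    characters = chars)
}

#' The bundled character definitions
#'
#' @return data frame with columns `index` and `name` for the 53
#'   developmental characters of the bundled matrix.
#' @export
fixture_characters <- function() {
  dir <- system.file("extdata", package = "ontochron", mustWork = TRUE)
  read.delim(file.path(dir, "table2_characters.tsv"))
}
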