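# Model file dialect
# ------------------
# TSV: `#` lines are comments; `#% species<TAB>name<TAB>nM[<TAB>input]`
# directive lines declare initial totals and input species; remaining rows
# have columns id|kind|lhs|mid|rhs|kon|koff|kcat, with `+`-separated species
# and `n*`-prefixed stoichiometry in the side columns.
# JSON mirror: {"species":[{"name","initial_total","is_input"}],
#               "schemes":[{"id","kind","lhs","mid","rhs","kon","koff","kcat"}]}.

#' Parse a reaction-system description
#'
#' Accepts the package's TSV dialect or its JSON mirror (autodetected: text
#' starting with `{` is JSON). See `vignette("psf-methods")` for the format.
#'
#' @param text character: either the file content (possibly multi-line) or a
#'   path to a file.
#' @return a `reaction_system`.
#' @export
parse_model <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  text <- paste(text, collapse = "\n")
  if (grepl("^\\s*\\{", text)) parse_model_json(text) else parse_model_tsv(text)
}

parse_model_tsv <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  species <- list(); schemes <- list(); inputs <- character()
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "#%")) {
      f <- strsplit(sub("^#%\\s*", "", line), "\t", fixed = TRUE)[[1]]
      if (length(f) < 3 || f[1] != "species") {
        abort(paste0("line ", ln, ": malformed directive '", line, "'"))
      }
      conc <- suppressWarnings(as.numeric(f[3]))
      if (is.na(conc)) abort(paste0("line ", ln, ": bad concentration '", f[3], "'"))
      species[[length(species) + 1]] <- tibble(name = f[2], initial_total = conc)
      if (length(f) >= 4 && f[4] == "input") inputs <- c(inputs, f[2])
      next
    }
    if (startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (identical(f[1], "id")) next  # header row
    if (length(f) < 5) abort(paste0("line ", ln, ": expected 8 tab-separated columns, got ",
                                    length(f)))
    f <- c(f, rep("", 8 - length(f)))  # strsplit drops trailing empty fields
    num <- function(x) if (!nzchar(trimws(x))) NULL else {
      v <- suppressWarnings(as.numeric(x))
      if (is.na(v)) abort(paste0("line ", ln, ": bad rate '", x, "'"))
      v
    }
    sch <- tryCatch(
      build_scheme(kind = f[2], lhs = f[3],
                   mid = if (nzchar(trimws(f[4]))) f[4] else NULL,
                   rhs = f[5], kon = num(f[6]), koff = num(f[7]), kcat = num(f[8]),
                   id = as.integer(f[1])),
      error = function(e) abort(paste0("line ", ln, ": ", conditionMessage(e))))
    schemes[[length(schemes) + 1]] <- sch
  }
  if (!length(schemes)) abort("no reaction rows found")
  reaction_system(bind_rows(species), bind_rows(schemes), inputs = inputs)
}

parse_model_json <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyDataFrame = TRUE)
  sp <- as_tibble(obj$species)
  schemes <- as_tibble(obj$schemes)
  for (col in c("kon", "koff", "kcat")) {
    if (!col %in% names(schemes)) schemes[[col]] <- NA_real_
  }
  if (!"mid" %in% names(schemes)) schemes$mid <- NA_character_
  built <- purrr::map(seq_len(nrow(schemes)), function(i) {
    r <- schemes[i, ]
    nn <- function(x) if (is.na(x)) NULL else x
    build_scheme(r$kind, r$lhs, r$rhs, mid = nn(r$mid), kon = nn(r$kon),
                 koff = nn(r$koff), kcat = nn(r$kcat), id = r$id)
  })
  inputs <- sp$name[isTRUE_vec(sp$is_input)]
  reaction_system(select(sp, "name", "initial_total"), bind_rows(built),
                  inputs = inputs)
}

#' Serialize a reaction system
#'
#' `write_model(parse_model(text))` is the identity up to formatting, and
#' `parse_model(write_model(sys))` reproduces `sys`'s species, schemes and
#' inputs (moieties are code-level annotations and are not serialized).
#'
#' @param system a `reaction_system`.
#' @param format `"tsv"` (default) or `"json"`.
#' @param path optional file path; when given, the text is also written there.
#' @return the serialized text, invisibly when `path` is given.
#' @export
write_model <- function(system, format = c("tsv", "json"), path = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    sp_lines <- sprintf("#%%\tspecies\t%s\t%s%s", system$species$name,
                        format(system$species$initial_total, trim = TRUE, scientific = NA),
                        ifelse(system$species$is_input, "\tinput", ""))
    hdr <- "id\tkind\tlhs\tmid\trhs\tkon\tkoff\tkcat"
    fmt <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE, scientific = NA, digits = 15))
    rows <- sprintf("%d\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                    system$schemes$id, system$schemes$kind, system$schemes$lhs,
                    ifelse(is.na(system$schemes$mid), "", system$schemes$mid),
                    system$schemes$rhs, fmt(system$schemes$kon),
                    fmt(system$schemes$koff), fmt(system$schemes$kcat))
    text <- paste(c("# psfkit model (TSV dialect)", sp_lines, hdr, rows, ""),
                  collapse = "\n")
  } else {
    text <- jsonlite::toJSON(list(
      species = system$species[, c("name", "initial_total", "is_input")],
      schemes = system$schemes), dataframe = "rows", na = "null",
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    text <- as.character(text)
  }
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}
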