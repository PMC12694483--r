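# CSV schemas shared by all pipeline stages. Every table is plain
# comma-separated UTF-8 with a header row; dates are ISO (YYYY-MM-DD).

schema_defs <- function() {
  list(
    soil = list(
      cols = c(
        year = "i", pattern = "c", n_rate = "d", replicate = "i", date = "D",
        depth_top_cm = "d", depth_bottom_cm = "d", bulk_density_g_cm3 = "d",
        no3_mg_kg = "d", nh4_mg_kg = "d"
      ),
      check = function(df) {
        c(
          row_problem(df$depth_bottom_cm <= df$depth_top_cm,
            "depth_bottom_cm must exceed depth_top_cm"),
          row_problem(df$bulk_density_g_cm3 <= 0, "bulk_density_g_cm3 must be > 0"),
          row_problem(df$no3_mg_kg < 0, "no3_mg_kg must be >= 0"),
          row_problem(df$nh4_mg_kg < 0, "nh4_mg_kg must be >= 0")
        )
      }
    ),
    plant = list(
      cols = c(
        year = "i", pattern = "c", n_rate = "d", replicate = "i", cut = "i",
        date = "D", leaf_n_pct = "d", stem_n_pct = "d",
        leaf_dm_kg_ha = "d", stem_dm_kg_ha = "d"
      ),
      check = function(df) {
        c(
          row_problem(df$leaf_n_pct < 0 | df$leaf_n_pct > 100,
            "leaf_n_pct must be in [0, 100]"),
          row_problem(df$stem_n_pct < 0 | df$stem_n_pct > 100,
            "stem_n_pct must be in [0, 100]"),
          row_problem(df$leaf_dm_kg_ha < 0, "leaf_dm_kg_ha must be >= 0"),
          row_problem(df$stem_dm_kg_ha < 0, "stem_dm_kg_ha must be >= 0"),
          row_problem(df$cut < 1, "cut must be >= 1")
        )
      }
    ),
    chamber = list(
      cols = c(
        year = "i", pattern = "c", n_rate = "d", replicate = "i", date = "D",
        position = "c", height_m = "d", temp_c = "d", minute = "d",
        conc_ul_l = "d"
      ),
      check = function(df) {
        c(
          row_problem(!df$position %in% c("flat", "ridge", "furrow"),
            "position must be flat, ridge or furrow"),
          row_problem(df$height_m <= 0, "height_m must be > 0"),
          row_problem(df$temp_c <= -273, "temp_c must be > -273"),
          row_problem(df$minute < 0, "minute must be >= 0")
        )
      }
    ),
    flux = list(
      cols = c(
        year = "i", pattern = "c", n_rate = "d", replicate = "i", date = "D",
        position = "c", flux_ug_m2_h = "d", r_squared = "d", n_points = "i"
      ),
      check = function(df) {
        c(
          row_problem(df$n_points < 2, "n_points must be >= 2"),
          row_problem(!df$position %in% c("flat", "ridge", "furrow", "plot"),
            "position must be flat, ridge, furrow or plot")
        )
      }
    ),
    budget = list(
      cols = c(
        year = "i", pattern = "c", n_rate = "d", initial_soil_n = "d",
        soil_residue = "d", plant_accumulation = "d", n2o_emission = "d"
      ),
      check = function(df) {
        num <- c("n_rate", "initial_soil_n", "soil_residue",
          "plant_accumulation", "n2o_emission")
        unlist(lapply(num, function(v) {
          row_problem(df[[v]] < 0, paste0(v, " must be >= 0"))
        }))
      }
    )
  )
}

row_problem <- function(bad, msg) {
  bad <- which(!is.na(bad) & bad)
  if (length(bad) == 0) return(character())
  sprintf("row %d: %s", bad, msg)
}

#' Read and validate a pipeline CSV table
#'
#' Reads one of the pipeline's CSV schemas (`"soil"`, `"plant"`, `"chamber"`,
#' `"flux"`, `"budget"`), checking that every declared column is present, that
#' cells parse to the declared types, and that the schema's domain invariants
#' hold (e.g. positive bulk density, positions from the allowed set). Problems
#' are reported with row numbers.
#'
#' @param path Path to a CSV file.
#' @param schema Schema name.
#' @return A validated tibble with typed columns.
#' @seealso [write_table()]
#' @export
read_table <- function(path, schema = c("soil", "plant", "chamber", "flux", "budget")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "nbudget_io_error")
  }
  def <- schema_defs()[[schema]]
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(names(def$cols), header)
  if (length(missing) > 0) {
    abort(
      sprintf("%s schema: missing column(s) %s", schema,
        paste(missing, collapse = ", ")),
      class = "nbudget_schema_error"
    )
  }
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE)
  # cells are converted with base R's correctly rounded parsers so that
  # write_table()'s 17-digit output round-trips bit for bit
  df <- raw
  for (col in names(def$cols)) {
    x <- raw[[col]]
    parsed <- switch(def$cols[[col]],
      i = suppressWarnings(as.integer(x)),
      d = suppressWarnings(as.numeric(x)),
      D = as.Date(x, format = "%Y-%m-%d", optional = TRUE),
      c = x
    )
    bad <- which(is.na(parsed) & !is.na(x) & x != "NA")
    if (length(bad) > 0) {
      abort(
        sprintf("%s schema: %d cell(s) failed to parse; first at row %d, column %s",
          schema, length(bad), bad[1], col),
        class = "nbudget_parse_error"
      )
    }
    df[[col]] <- parsed
  }
  validate_table(df, schema)
}

#' Validate an in-memory table against a pipeline schema
#'
#' @param df A data frame.
#' @param schema Schema name, as in [read_table()].
#' @return `df` as a tibble, invisibly checked.
#' @export
validate_table <- function(df, schema = c("soil", "plant", "chamber", "flux", "budget")) {
  schema <- match.arg(schema)
  def <- schema_defs()[[schema]]
  missing <- setdiff(names(def$cols), names(df))
  if (length(missing) > 0) {
    abort(
      sprintf("%s schema: missing column(s) %s", schema,
        paste(missing, collapse = ", ")),
      class = "nbudget_schema_error"
    )
  }
  problems <- def$check(df)
  if (length(problems) > 0) {
    abort(
      sprintf("%s schema: %d invariant violation(s):\n%s", schema,
        length(problems), paste(head(problems, 10), collapse = "\n")),
      class = "nbudget_validation_error"
    )
  }
  tibble::as_tibble(df)
}

#' Write a pipeline table to CSV
#'
#' Validates against the schema, then writes plain CSV so that
#' `read_table(write_table(x))` round-trips exactly.
#'
#' @inheritParams validate_table
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, schema = c("soil", "plant", "chamber", "flux", "budget")) {
  schema <- match.arg(schema)
  def <- schema_defs()[[schema]]
  df <- validate_table(df, schema)[names(def$cols)]
  # doubles are written with 17 significant digits so that reading the file
  # back reproduces the records bit for bit
  for (col in names(def$cols)[def$cols == "d"]) {
    df[[col]] <- ifelse(is.na(df[[col]]), NA_character_,
      sprintf("%.17g", df[[col]]))
  }
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
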