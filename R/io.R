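#' Write a gridded field (or several) as long-format CSV
#'
#' Columns `lon`, `lat` (cell centres) plus one column per named field.
#'
#' @param grid A `world_grid`.
#' @param fields A matrix or named list of matrices.
#' @param path Output CSV path.
#' @export
write_grid_csv <- function(grid, fields, path) {
  if (is.matrix(fields)) fields <- list(value = fields)
  df <- data.frame(lon = rep(grid$lon, each = grid$n_lat),
                   lat = rep(grid$lat, times = grid$n_lon))
  for (nm in names(fields)) df[[nm]] <- as.vector(fields[[nm]])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format gridded CSV back onto a grid
#'
#' @param grid The `world_grid` the file was written from.
#' @param path CSV path.
#' @return Named list of matrices (one per value column).
#' @export
read_grid_csv <- function(grid, path) {
  df <- utils::read.csv(path)
  cell <- grid_cell_id(grid, df$lon, df$lat)
  cols <- setdiff(names(df), c("lon", "lat"))
  out <- lapply(cols, function(nm) {
    m <- empty_field(grid, NA_real_)
    m[cell] <- df[[nm]]
    m
  })
  stats::setNames(out, cols)
}

#' Write activity records as CSV
#'
#' Columns: vessel_id, ISO-8601 timestamp, lon, lat, speed_mps.
#'
#' @param records A `vessel_activity` data.frame.
#' @param path Output path.
#' @export
write_activity_csv <- function(records, path) {
  out <- records
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read activity records from CSV
#'
#' @param path CSV path with columns vessel_id, timestamp, lon, lat,
#'   speed_mps.
#' @return A `vessel_activity` data.frame.
#' @export
read_activity_csv <- function(path) {
  df <- utils::read.csv(path)
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  class(df) <- c("vessel_activity", "data.frame")
  df
}

#' Write fuel-policy regions as GeoJSON
#'
#' @param policy A `fuel_policy`.
#' @param path Output path.
#' @export
write_policy_geojson <- function(policy, path) {
  features <- lapply(policy$regions, function(r) {
    ring <- rbind(r$polygon, r$polygon[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(name = r$name %||% "region", s_cap = r$s_cap,
                           effective_date = format(r$effective_date)),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) unname(ring[i, ])))))
  })
  gj <- list(type = "FeatureCollection",
             properties = list(scenario = policy$scenario,
                               global_s_frac = policy$global_s_frac),
             features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read fuel-policy regions from GeoJSON
#'
#' @param path GeoJSON path written by [write_policy_geojson()].
#' @return A `fuel_policy`.
#' @export
read_policy_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  regions <- lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) unlist(p)))
    list(name = f$properties$name,
         polygon = ring[-nrow(ring), , drop = FALSE],
         s_cap = f$properties$s_cap,
         effective_date = as.Date(f$properties$effective_date))
  })
  pol <- fuel_policy(gj$properties$scenario, regions)
  pol$global_s_frac <- gj$properties$global_s_frac
  pol
}

#' Write all pipeline outputs to a directory
#'
#' Per scenario: emission species and total-PM2.5 grids as CSV; burden
#' tables as CSV; a comparison bundle when BAU and ACTION_2020 both ran;
#' the run manifest as JSON.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- result$world$grid
  for (sc in names(result$runs)) {
    run <- result$runs[[sc]]
    write_grid_csv(grid, run$emissions$species,
                   file.path(out_dir, paste0("emissions_", sc, ".csv")))
    write_grid_csv(grid, list(pm25_total = run$concentration$total),
                   file.path(out_dir, paste0("pm25_", sc, ".csv")))
    if (!is.null(run$burdens)) {
      tabs <- do.call(rbind, lapply(names(run$burdens), function(ep) {
        agg <- aggregate_burden(run$burdens[[ep]])
        cbind(endpoint = ep, agg$country)
      }))
      utils::write.csv(tabs,
                       file.path(out_dir, paste0("burden_", sc, ".csv")),
                       row.names = FALSE)
    }
  }
  if (all(c("BAU", "ACTION_2020") %in% names(result$runs))) {
    cmp <- compare_scenarios(result)
    utils::write.csv(cmp$emissions,
                     file.path(out_dir, "compare_emissions.csv"),
                     row.names = FALSE)
    if (!is.null(cmp$health)) {
      utils::write.csv(cmp$health, file.path(out_dir, "compare_health.csv"),
                       row.names = FALSE)
    }
    if (!is.null(cmp$forcing)) {
      utils::write.csv(cmp$forcing, file.path(out_dir, "compare_forcing.csv"),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
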