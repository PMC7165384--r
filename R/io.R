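# Flat-file interfaces: CSV tables, GeoJSON window/partition polygons,
# YAML configuration, coordinate-format sparse matrices.

#' Write / read a case table as CSV
#'
#' Columns: x_km, y_km, age_group, year, group, error_class.
#' @param cases a [simulate_cases()] table.
#' @param path output file.
#' @export
write_cases_csv <- function(cases, path) {
  out <- data.frame(x_km = cases$x, y_km = cases$y,
                    age_group = cases$age_group, year = cases$year,
                    group = cases$group, error_class = cases$error_class)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cases_csv
#' @export
read_cases_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(data.frame(x = d$x_km, y = d$y_km, age_group = d$age_group,
                       year = d$year, group = d$group,
                       error_class = d$error_class),
            class = c("case_set", "data.frame"))
}

#' Write / read a population panel as long-format CSV (i, j, k, count)
#' @param panel array \[age group, year, cell\].
#' @param path output file.
#' @export
write_panel_csv <- function(panel, path) {
  dn <- dimnames(panel)
  out <- expand.grid(i = dn[[1]], j = dn[[2]], k = dn[[3]],
                     stringsAsFactors = FALSE)
  out$count <- as.vector(panel)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = c(i = "character", j = "character",
                                            k = "character"))
  ages <- unique(d$i); yrs <- unique(d$j); ks <- unique(d$k)
  arr <- array(0, dim = c(length(ages), length(yrs), length(ks)),
               dimnames = list(ages, yrs, ks))
  arr[cbind(match(d$i, ages), match(d$j, yrs), match(d$k, ks))] <- d$count
  arr
}

#' Write an expected-count surface as CSV (k, x_km, y_km, E)
#' @param expected an [expected_cases()] surface.
#' @param path output file.
#' @export
write_expected_csv <- function(expected, path) {
  out <- data.frame(k = expected$k,
                    x_km = if (!is.null(expected$x)) expected$x else NA,
                    y_km = if (!is.null(expected$y)) expected$y else NA,
                    E = expected$E)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write the observation window (or a partition) as GeoJSON polygons
#' @param grid a [make_grid()] object.
#' @param path output file.
#' @export
write_window_geojson <- function(grid, path) {
  ring <- lapply(seq_len(nrow(grid$window)),
                 function(i) as.numeric(grid$window[i, ]))
  gj <- list(type = "FeatureCollection",
             features = list(list(
               type = "Feature",
               properties = list(name = "observation_window"),
               geometry = list(type = "Polygon", coordinates = list(ring)))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_window_geojson
#' @param partition a [make_partition()] object.
#' @export
write_partition_geojson <- function(partition, grid, path) {
  feats <- lapply(seq_len(partition$n_areas), function(a) {
    ax <- (a - 1L) %% partition$nbx
    ay <- (a - 1L) %/% partition$nbx
    bw <- grid$nx * grid$cell_km / partition$nbx
    bh <- grid$ny * grid$cell_km / partition$nby
    x0 <- grid$origin[1] + ax * bw; y0 <- grid$origin[2] + ay * bh
    ring <- list(c(x0, y0), c(x0 + bw, y0), c(x0 + bw, y0 + bh),
                 c(x0, y0 + bh), c(x0, y0))
    list(type = "Feature", properties = list(area = a),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the mesh as a CSV pair (nodes, triangles)
#' @param mesh a [build_mesh()] object.
#' @param nodes_path,triangles_path output files.
#' @export
write_mesh_csv <- function(mesh, nodes_path, triangles_path) {
  utils::write.csv(data.frame(node = seq_len(nrow(mesh$nodes)),
                              x_km = mesh$nodes[, 1], y_km = mesh$nodes[, 2]),
                   nodes_path, row.names = FALSE)
  utils::write.csv(data.frame(v1 = mesh$triangles[, 1],
                              v2 = mesh$triangles[, 2],
                              v3 = mesh$triangles[, 3]),
                   triangles_path, row.names = FALSE)
  invisible(nodes_path)
}

#' Write a sparse matrix in coordinate (triplet) text format
#' @param m a sparse Matrix.
#' @param path output file.
#' @export
write_sparse_coord <- function(m, path) {
  tm <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
  utils::write.csv(data.frame(i = tm@i + 1L, j = tm@j + 1L, x = tm@x),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write / read an experiment configuration as YAML
#' @param cfg an [experiment_config()] object.
#' @param path output file.
#' @export
write_config_yaml <- function(cfg, path) {
  # yaml drops names of atomic vectors; promote them to maps
  promote <- function(x) {
    if (is.list(x)) lapply(x, promote)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(promote(unclass(cfg)), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  sc <- raw$scenario
  scenario <- scenario_config(
    age_groups = sc$age_groups, years = sc$years[1]:sc$years[length(sc$years)],
    census_years = unlist(sc$census_years),
    target_total_cases = sc$target_total_cases,
    target_birth_cases = sc$target_birth_cases,
    pop_per_agegroup = sc$pop_per_agegroup,
    covariate_sds = unlist(sc$covariate_sds),
    true_beta = unlist(sc$true_beta),
    true_sigma = sc$true_sigma, true_rho = sc$true_rho,
    window_km = unlist(sc$window_km), cell_km = sc$cell_km,
    seed = sc$seed)
  experiment_config(scenario = scenario,
                    mesh_spacing = raw$mesh_spacing,
                    mesh_buffer = raw$mesh_buffer,
                    block_km = raw$block_km,
                    n_draws = raw$n_draws,
                    variants = unlist(raw$variants),
                    sensitivity_medians = unlist(raw$sensitivity_medians),
                    out_dir = raw$out_dir,
                    seed = raw$seed)
}
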