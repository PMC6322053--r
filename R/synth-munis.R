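#' Classify a municipality by population size
#'
#' Three classes: metropolitan (more than 250,000 inhabitants), urban
#' (20,000 to 250,000) and rural (fewer than 20,000).
#'
#' @param population numeric vector of inhabitant counts.
#' @return character vector in `{"metropolitan", "urban", "rural"}`.
#' @export
classify_municipality <- function(population) {
  ifelse(population > 250000, "metropolitan",
         ifelse(population >= 20000, "urban", "rural"))
}

#' Partition the grid into synthetic municipalities
#'
#' Cells are partitioned into contiguous municipalities by seeded region
#' growing (every cell ends up in exactly one municipality). Each member cell
#' receives a built-up area `A_ip` (a random fraction of the cell area), the
#' change-of-support weight carrier. Populations are drawn so that all three
#' size classes occur.
#'
#' @param grid a [grid_spec()].
#' @param n_munis number of municipalities, at most `n_cells(grid)`.
#' @param builtup_params list with `logit_mean` and `logit_sd` controlling the
#'   per-cell built-up fraction `plogis(rnorm(logit_mean, logit_sd))`.
#' @param class_probs target proportions of metropolitan/urban/rural
#'   municipalities (at least one of each is forced).
#' @param seed integer seed.
#' @return list of class `muni_set` with `munis` (municipality_id, population,
#'   size_class, n_cells) and `cells` (municipality_id, cell_i, cell_j,
#'   builtup_area_km2).
#' @export
make_municipalities <- function(grid, n_munis,
                                builtup_params = list(logit_mean = -2.2,
                                                      logit_sd = 1),
                                class_probs = c(metropolitan = 0.04,
                                                urban = 0.26, rural = 0.70),
                                seed = 1) {
  nc <- n_cells(grid)
  if (n_munis > nc) stop("n_munis exceeds the number of grid cells")
  if (n_munis < 1) stop("n_munis must be >= 1")
  set.seed(seed)
  assign <- integer(nc)  # 0 = unassigned
  seeds <- sample.int(nc, n_munis)
  assign[seeds] <- seq_len(n_munis)
  # 4-neighbour adjacency on the (i fastest) linear index
  nbrs <- function(idx) {
    i <- (idx - 1L) %% grid$nx
    j <- (idx - 1L) %/% grid$nx
    out <- c(if (i > 0) idx - 1L, if (i < grid$nx - 1L) idx + 1L,
             if (j > 0) idx - grid$nx, if (j < grid$ny - 1L) idx + grid$nx)
    out
  }
  frontier <- lapply(seq_len(n_munis), function(m) seeds[m])
  remaining <- sum(assign == 0L)
  while (remaining > 0L) {
    grew <- FALSE
    for (m in sample.int(n_munis)) {
      fr <- frontier[[m]]
      if (!length(fr)) next
      cand <- unique(unlist(lapply(fr, nbrs)))
      cand <- cand[assign[cand] == 0L]
      if (!length(cand)) { frontier[[m]] <- integer(0); next }
      pick <- cand[sample.int(length(cand), 1L)]
      assign[pick] <- m
      frontier[[m]] <- c(fr, pick)
      remaining <- remaining - 1L
      grew <- TRUE
      if (remaining == 0L) break
    }
    if (!grew && remaining > 0L)
      stop("region growing stalled")  # cannot happen on a connected grid
  }
  cc <- cell_centers(grid)
  frac <- stats::plogis(stats::rnorm(nc, builtup_params$logit_mean,
                                     builtup_params$logit_sd))
  cells <- data.frame(municipality_id = sprintf("M%04d", assign),
                      cell_i = cc$cell_i, cell_j = cc$cell_j,
                      builtup_area_km2 = frac * grid$cell_km^2,
                      stringsAsFactors = FALSE)
  cells <- cells[order(cells$municipality_id), ]
  rownames(cells) <- NULL
  # size classes: force at least one of each, then draw populations in-range
  p <- class_probs / sum(class_probs)
  n_met <- max(1L, round(p[["metropolitan"]] * n_munis))
  n_urb <- max(1L, round(p[["urban"]] * n_munis))
  if (n_munis < 3L) { n_met <- min(n_met, 1L); n_urb <- min(n_urb, 1L) }
  n_rur <- max(n_munis - n_met - n_urb, 0L)
  cls <- sample(rep(c("metropolitan", "urban", "rural"),
                    c(n_met, n_urb, n_rur))[seq_len(n_munis)])
  pop <- numeric(n_munis)
  pop[cls == "metropolitan"] <- round(exp(stats::runif(sum(cls == "metropolitan"),
                                                       log(260000), log(2.5e6))))
  pop[cls == "urban"] <- round(exp(stats::runif(sum(cls == "urban"),
                                                log(20000), log(250000))))
  pop[cls == "rural"] <- round(exp(stats::runif(sum(cls == "rural"),
                                                log(500), log(19500))))
  munis <- data.frame(municipality_id = sprintf("M%04d", seq_len(n_munis)),
                      population = pop,
                      size_class = classify_municipality(pop),
                      n_cells = as.integer(table(factor(assign,
                                                        seq_len(n_munis)))),
                      stringsAsFactors = FALSE)
  structure(list(munis = munis, cells = cells, grid = grid),
            class = "muni_set")
}

#' @export
print.muni_set <- function(x, ...) {
  cat(sprintf("muni_set: %d municipalities over %d cells (%s)\n",
              nrow(x$munis), nrow(x$cells),
              paste(names(table(x$munis$size_class)),
                    table(x$munis$size_class), collapse = ", ")))
  invisible(x)
}
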