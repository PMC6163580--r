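#' Build a named fixture geometry
#'
#' Dispatcher over the synthetic-geometry generators, used by the `fixtures`
#' command-line subcommand. Extra arguments are passed to the generator.
#'
#' @param kind one of `"strand"`, `"sheet"`, `"barrel"`, `"coil"`,
#'   `"cylinder_protein"`, `"detergent_shell"`.
#' @param ... generator arguments; `detergent_shell` builds its protein
#'   with [bacteriorhodopsin_mimic()] unless a `protein` argument is given.
#' @return list with `system` and `frame`.
#' @export
make_fixture <- function(kind = c("strand", "sheet", "barrel", "coil",
                                  "cylinder_protein", "detergent_shell"),
                         ...) {
  kind <- match.arg(kind)
  args <- list(...)
  switch(kind,
    strand = do.call(make_strand, args),
    sheet = do.call(make_sheet, args),
    barrel = do.call(make_barrel, args),
    coil = do.call(make_coil, args),
    cylinder_protein = do.call(make_cylinder_protein, args),
    detergent_shell = {
      if (is.null(args$protein)) args$protein <- bacteriorhodopsin_mimic()
      do.call(make_detergent_shell, args)
    }
  )
}

#' Write a fixture as GRO plus a manifest
#'
#' Writes `<prefix>.gro` and `<prefix>.manifest.yaml`; the manifest records
#' the fixture kind and every generator parameter (seed included) so the
#' file can be regenerated bit-identically.
#'
#' @param fixture a `list(system, frame)` fixture.
#' @param prefix output path prefix.
#' @param kind fixture kind recorded in the manifest.
#' @param params named list of generator parameters recorded in the
#'   manifest.
#' @return character vector of the two paths written.
#' @export
write_fixture <- function(fixture, prefix, kind, params = list()) {
  gro <- paste0(prefix, ".gro")
  man <- paste0(prefix, ".manifest.yaml")
  write_gro(fixture$system, fixture$frame, gro, title = paste("fixture", kind))
  yaml::write_yaml(c(list(kind = kind), params), man)
  c(gro, man)
}
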