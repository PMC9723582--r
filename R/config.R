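# Flat key=value serialization of the full pipeline configuration.

.PARAM_STAGES <- c(construct = "ConstructModel", segment = "SegmentParam",
                   consensus = "ConsensusParam", cluster = "ClusterParam",
                   refine = "RefineParam", resolve = "ResolveParam")

#' Write a pipeline configuration to a plain-text file
#'
#' One `stage.slot = value` line per parameter; vectors are comma-separated.
#' The file round-trips through [readPipelineParam()].
#'
#' @param param a [PipelineParam-class].
#' @param path output path.
#' @export
writePipelineParam <- function(param, path) {
  lines <- character(0)
  for (stage in names(.PARAM_STAGES)) {
    obj <- slot(param, stage)
    for (sn in slotNames(obj)) {
      val <- slot(obj, sn)
      lines <- c(lines, sprintf("%s.%s = %s", stage, sn,
                                paste(format(val, digits = 15), collapse = ",")))
    }
  }
  lines <- c(lines, sprintf("seed = %d", param@seed))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pipeline configuration written by [writePipelineParam()]
#'
#' @param path config file path.
#' @return a [PipelineParam-class]; every threshold is re-validated on read.
#' @export
readPipelineParam <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- regmatches(lines,
                   regexec("^[[:space:]]*([^=[:space:]]+)[[:space:]]*=[[:space:]]*(.*)$",
                           lines))
  if (any(lengths(kv) != 3L)) stop("malformed config line")
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  stages <- lapply(names(.PARAM_STAGES), function(stage) {
    obj <- if (stage == "construct") .defaultConstructRaw()
           else new(.PARAM_STAGES[[stage]])
    pick <- startsWith(keys, paste0(stage, "."))
    for (i in which(pick)) {
      sn <- sub(paste0("^", stage, "\\."), "", keys[i])
      if (!sn %in% slotNames(obj)) stop("unknown config key: ", keys[i])
      cur <- slot(obj, sn)
      raw <- trimws(strsplit(vals[i], ",", fixed = TRUE)[[1]])
      raw[raw == "NA"] <- NA_character_
      slot(obj, sn) <- if (is.integer(cur)) as.integer(raw)
                       else if (is.numeric(cur)) as.numeric(raw)
                       else raw
    }
    validObject(obj)
    obj
  })
  names(stages) <- names(.PARAM_STAGES)
  seed <- if (any(keys == "seed")) as.integer(vals[keys == "seed"][1L]) else 1L
  PipelineParam(construct = stages$construct, segment = stages$segment,
                consensus = stages$consensus, cluster = stages$cluster,
                refine = stages$refine, resolve = stages$resolve, seed = seed)
}
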