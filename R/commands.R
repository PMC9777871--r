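#' The SF/TR/PR command protocol
#'
#' Networks are driven by a line-oriented textual protocol. Every fact and
#' rule carries a 32-hex-character GUID and commands address facts by GUID:
#'
#' * `SF:{guid}=DDD.DDD` - set fact: assign a value to one fact.
#' * `TR:{start},{output}=DDD.DDD` - train: set the start fact to the carried
#'   value, then run one training update toward the configured target.
#' * `PR:{start},{output}=DDD.DDD` - present: set the start fact and return
#'   the output fact's value.
#'
#' Values are fixed-point `DDD.DDD` strings (see [format_gdes_value()]); the
#' system only emits values in `[0, 1]`, e.g. `000.393`.
#'
#' @param line A single command line.
#' @return `parse_command()` returns a `gdes_command` (a list with `kind`,
#'   `fact_guids`, `value`); `format_command()` returns the command line.
#' @examples
#' cmd <- parse_command("SF:{24da3290-e934-4a9c-84e9-6a0d856e5073}=000.393")
#' cmd$value
#' format_command(cmd)
#' @name gdes_commands
NULL

#' @param kind `"SF"`, `"TR"` or `"PR"`.
#' @param fact_guids One GUID for SF; start and output fact GUIDs for TR/PR.
#' @param value Numeric value carried by the command.
#' @rdname gdes_commands
#' @export
gdes_command <- function(kind, fact_guids, value) {
  kind <- match.arg(kind, c("SF", "TR", "PR"))
  n_expected <- if (kind == "SF") 1L else 2L
  if (length(fact_guids) != n_expected) {
    stop(kind, " commands carry ", n_expected, " fact GUID(s)", call. = FALSE)
  }
  if (!all(is_guid(fact_guids))) {
    stop("malformed GUID: ", fact_guids[!is_guid(fact_guids)][1], call. = FALSE)
  }
  stopifnot(is.numeric(value), length(value) == 1, value >= 0, value <= 999.999)
  structure(
    list(kind = kind, fact_guids = unname(fact_guids), value = quantize_value(value)),
    class = "gdes_command"
  )
}

#' @rdname gdes_commands
#' @export
parse_command <- function(line) {
  stopifnot(is.character(line), length(line) == 1, nzchar(line))
  m <- regexec(
    "^(SF|TR|PR):\\{([0-9a-f-]+)\\}(?:,\\{([0-9a-f-]+)\\})?=([0-9]{3}\\.[0-9]{3})$",
    line
  )
  g <- regmatches(line, m)[[1]]
  if (length(g) == 0) {
    # pin down what failed so the error can name a position
    if (!grepl("^(SF|TR|PR):", line)) {
      stop("cannot parse command (unknown kind) at position 1: ", line, call. = FALSE)
    }
    if (!grepl("=[0-9]{3}\\.[0-9]{3}$", line)) {
      stop(
        "malformed value (need DDD.DDD) at position ",
        regexpr("=", line)[1] + 1, ": ", line,
        call. = FALSE
      )
    }
    stop("malformed GUID at position 4: ", line, call. = FALSE)
  }
  kind <- g[2]
  guids <- c(g[3], g[4])
  guids <- guids[nzchar(guids)]
  if (!all(is_guid(guids))) {
    stop("malformed GUID at position 4: ", line, call. = FALSE)
  }
  if (kind == "SF" && length(guids) != 1 || kind != "SF" && length(guids) != 2) {
    stop(kind, " command carries the wrong number of GUIDs: ", line, call. = FALSE)
  }
  gdes_command(kind, guids, as.numeric(g[5]))
}

#' @param command A `gdes_command`.
#' @rdname gdes_commands
#' @export
format_command <- function(command) {
  stopifnot(inherits(command, "gdes_command"))
  guids <- paste0("{", command$fact_guids, "}", collapse = ",")
  paste0(command$kind, ":", guids, "=", format_gdes_value(command$value))
}

#' @export
print.gdes_command <- function(x, ...) {
  cat(format_command(x), "\n")
  invisible(x)
}

#' Replay a command script against a network
#'
#' Executes SF/TR/PR command lines in order. The trial engine can emit the
#' full script it ran, and replaying that script on a fresh network with the
#' same design reproduces the trained weights bit-identically.
#'
#' @param network A `gdes_network`.
#' @param lines Character vector of command lines (blank lines and lines
#'   starting with `#` are skipped).
#' @param target Training target used by TR commands (default 0.5).
#' @param velocity Learning rate used by TR commands (default 0.1).
#' @return A list with `network` (final state) and `pr_outputs` (numeric
#'   vector of every PR command's output, in order).
#' @export
run_script <- function(network, lines, target = 0.5, velocity = 0.1) {
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  pr_outputs <- numeric(0)
  for (line in lines) {
    cmd <- parse_command(line)
    if (cmd$kind == "SF") {
      network <- set_fact(network, cmd$fact_guids[1], cmd$value)
    } else if (cmd$kind == "TR") {
      step <- train_step(
        network,
        start_value = cmd$value, target = target,
        velocity = velocity, end_fact = cmd$fact_guids[2]
      )
      network <- step$network
    } else {
      network <- propagate(network, start_value = cmd$value)
      pr_outputs <- c(pr_outputs, fact_value(network, cmd$fact_guids[2]))
    }
  }
  list(network = network, pr_outputs = pr_outputs)
}
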