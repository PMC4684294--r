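# Classed conditions so the command-line layer can map failures to exit codes.

ns_error <- function(msg, class) {
  stop(structure(class = c(class, "netsilent_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

ns_input_error <- function(msg) ns_error(msg, "netsilent_input_error")

ns_convergence_error <- function(msg) ns_error(msg, "netsilent_convergence_error")

# statistical degeneracy, e.g. single-class labels
ns_degenerate_error <- function(msg) ns_error(msg, "netsilent_degenerate_error")
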