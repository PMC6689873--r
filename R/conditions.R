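## Structured error conditions used across the package.

mkCondition <- function(class, msg, ...) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = NULL, ...))
}

mixtureRejected <- function(msg = "input is a mixture or salt (multiple fragments)")
  mkCondition("MixtureRejected", msg)

inorganicRejected <- function(msg = "input contains no carbon atom")
  mkCondition("InorganicRejected", msg)

invalidStructure <- function(msg)
  mkCondition("InvalidStructure", msg)

parameterError <- function(msg)
  mkCondition("ParameterError", msg)

schemaError <- function(msg, pointer = NULL)
  mkCondition("SchemaError",
              if (is.null(pointer)) msg else sprintf("%s (at %s)", msg, pointer),
              pointer = pointer)

referenceError <- function(msg)
  mkCondition("ReferenceError", msg)

ruleCompileError <- function(ruleId, msg)
  mkCondition("RuleCompileError", sprintf("rule '%s': %s", ruleId, msg),
              ruleId = ruleId)

trainingError <- function(msg)
  mkCondition("TrainingError", msg)

reasoningError <- function(msg)
  mkCondition("ReasoningError", msg)
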