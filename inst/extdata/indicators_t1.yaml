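# Indicator specification for task T1 of the synthetic air-conditioner
# style task.  Eight indicators: per-role activeness counts, direct
# presence indicators, inferred ordered sequences, the interactive
# chat-block count and the task outcome.
events:
  - task start
  - task end
  - chat
  - controlA
  - controlB
  - controlC
  - controlD
  - apply
  - task result
indicators:
  - name: T1A01
    level: A
    output: count
    element: Action
    rule: {type: count_events}
    conversion: {kind: empirical_mean_minus_sd}
  - name: T1A02
    level: A
    output: binary
    element: Task regulation
    rule: {type: presence, event: controlA}
  - name: T1A03
    level: A
    output: binary
    element: Systematicity
    rule: {type: sequence, events: [controlB, apply]}
  - name: T1B01
    level: B
    output: count
    element: Action
    rule: {type: count_events}
    conversion: {kind: empirical_mean_minus_sd}
  - name: T1B02
    level: B
    output: binary
    element: Task regulation
    rule: {type: presence, event: controlC}
  - name: T1B03
    level: B
    output: binary
    element: Systematicity
    rule: {type: sequence, events: [controlD, apply]}
  - name: T1G01
    level: G
    output: binary
    element: Goal attainment
    rule: {type: outcome, event: task result, pattern: success}
  - name: T1G02
    level: G
    output: count
    element: Interaction
    rule: {type: chat_blocks}
    conversion: {kind: fixed, cutoff: 2}
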