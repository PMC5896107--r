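# Default CV-usage rules: each location's term must descend (is_a) from the ancestor.
location	required_ancestor	severity
experiment.detection_method	MI:0001	error
interaction.interaction_type	MI:0190	error
participant.biological_role	MI:0500	error
participant.experimental_role	MI:0495	error
interactor.interactor_type	MI:0313	error
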