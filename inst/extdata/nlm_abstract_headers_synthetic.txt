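# Curated stand-in for the National Library of Medicine structured-abstract
# section label list (synthetic subset assembled from common labels; the
# full NLM list can be supplied instead via the `headers` argument /
# --headers option). One uppercase header per line. Compiled: 2026-09.
AIM
AIMS
AIM OF THE STUDY
BACKGROUND
BACKGROUND AND AIMS
BACKGROUND AND OBJECTIVES
BACKGROUND AND PURPOSE
CONCLUSION
CONCLUSIONS
CONCLUSIONS AND RELEVANCE
CONTEXT
DESIGN
DESIGN AND SETTING
DISCUSSION
FINDINGS
FUNDING
HYPOTHESIS
IMPORTANCE
INTERPRETATION
INTERVENTION
INTERVENTIONS
INTRODUCTION
LIMITATIONS
MAIN OUTCOME MEASURES
MAIN OUTCOMES AND MEASURES
MAIN RESULTS
MATERIALS AND METHODS
MEASUREMENTS
METHOD
METHODS
METHODS AND RESULTS
OBJECT
OBJECTIVE
OBJECTIVES
OUTCOME MEASURES
OUTCOMES
PARTICIPANTS
PATIENTS
PATIENTS AND METHODS
PURPOSE
RATIONALE
RESULTS
SETTING
SETTINGS
STUDY DESIGN
STUDY OBJECTIVE
SUBJECTS
SUBJECTS AND METHODS
SUMMARY
TRIAL DESIGN
TRIAL REGISTRATION
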