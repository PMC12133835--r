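# Synthetic DSM-5-style depression screening criteria statements.
# One statement per line; lines starting with '#' are ignored.
# These paraphrased statements are shipped for testing and demonstration;
# substitute a clinically vetted criteria file for real screening use.
persistent sadness or low mood for most of the day nearly every day
markedly diminished interest or pleasure in almost all activities
significant change in appetite or body weight without dieting
insomnia or sleeping far more than usual nearly every day
restlessness or slowed movement noticeable to other people
fatigue or loss of energy nearly every day
feelings of worthlessness or excessive inappropriate guilt
diminished ability to think or concentrate and indecisiveness
recurrent thoughts of death or of wanting to hurt oneself
expressions of feeling hurt broken moody bored or full of anger and sadness
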