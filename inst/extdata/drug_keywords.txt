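xanax
zanax
xans
bars
whitebar
oxy
oxi
percocet
percocert
adderall
adderrall
hydrocodone
codeine
fentanyl
valium
lsd
acid
mdma
molly
opioid
painkiller
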