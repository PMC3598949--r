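side,load,basis,cap,tooth,percent,mark
left,incisive,volume,coronal,canine,42.2,exception
left,incisive,volume,coronal,first_premolar,69.3,
left,incisive,volume,coronal,second_premolar,74.1,
left,incisive,volume,coronal,second_molar,12.6,exception
left,incisive,volume,apical,canine,24.2,
left,incisive,volume,apical,first_premolar,44.6,
left,incisive,volume,apical,second_premolar,32.0,
left,incisive,volume,apical,second_molar,8.0,
left,incisive,bru,coronal,canine,57.9,
left,incisive,bru,coronal,first_premolar,79.1,
left,incisive,bru,coronal,second_premolar,73.8,
left,incisive,bru,coronal,second_molar,9.6,bru_exception
left,incisive,bru,apical,canine,22.4,
left,incisive,bru,apical,first_premolar,45.2,
left,incisive,bru,apical,second_premolar,25.0,
left,incisive,bru,apical,second_molar,5.6,
left,unilateral_molar,volume,coronal,canine,38.4,exception
left,unilateral_molar,volume,coronal,first_premolar,78.5,
left,unilateral_molar,volume,coronal,second_premolar,75.4,
left,unilateral_molar,volume,coronal,second_molar,6.5,exception
left,unilateral_molar,volume,apical,canine,20.3,
left,unilateral_molar,volume,apical,first_premolar,50.2,exception
left,unilateral_molar,volume,apical,second_premolar,31.0,
left,unilateral_molar,volume,apical,second_molar,15.0,
left,unilateral_molar,bru,coronal,canine,51.0,
left,unilateral_molar,bru,coronal,first_premolar,89.0,
left,unilateral_molar,bru,coronal,second_premolar,67.8,
left,unilateral_molar,bru,coronal,second_molar,2.9,bru_exception
left,unilateral_molar,bru,apical,canine,14.5,
left,unilateral_molar,bru,apical,first_premolar,46.7,
left,unilateral_molar,bru,apical,second_premolar,24.4,
left,unilateral_molar,bru,apical,second_molar,26.8,
right,incisive,volume,coronal,canine,84.5,
right,incisive,volume,coronal,first_premolar,56.1,
right,incisive,volume,coronal,second_premolar,71.4,
right,incisive,volume,coronal,second_molar,4.1,exception
right,incisive,volume,apical,canine,16.4,
right,incisive,volume,apical,first_premolar,61.0,exception
right,incisive,volume,apical,second_premolar,43.5,
right,incisive,volume,apical,second_molar,72.0,exception
right,incisive,bru,coronal,canine,89.4,
right,incisive,bru,coronal,first_premolar,74.7,
right,incisive,bru,coronal,second_premolar,79.7,
right,incisive,bru,coronal,second_molar,0.8,bru_exception
right,incisive,bru,apical,canine,16.8,
right,incisive,bru,apical,first_premolar,51.7,bru_exception_near
right,incisive,bru,apical,second_premolar,54.0,bru_exception_near
right,incisive,bru,apical,second_molar,46.6,
right,unilateral_molar,volume,coronal,canine,56.0,
right,unilateral_molar,volume,coronal,first_premolar,37.9,exception
right,unilateral_molar,volume,coronal,second_premolar,62.1,
right,unilateral_molar,volume,coronal,second_molar,47.9,exception
right,unilateral_molar,volume,apical,canine,12.7,
right,unilateral_molar,volume,apical,first_premolar,52.8,exception
right,unilateral_molar,volume,apical,second_premolar,73.8,exception
right,unilateral_molar,volume,apical,second_molar,76.4,exception
right,unilateral_molar,bru,coronal,canine,64.5,
right,unilateral_molar,bru,coronal,first_premolar,39.8,bru_exception
right,unilateral_molar,bru,coronal,second_premolar,67.3,
right,unilateral_molar,bru,coronal,second_molar,49.6,bru_exception_near
right,unilateral_molar,bru,apical,canine,6.5,
right,unilateral_molar,bru,apical,first_premolar,52.4,bru_exception_near
right,unilateral_molar,bru,apical,second_premolar,52.9,bru_exception_near
right,unilateral_molar,bru,apical,second_molar,64.5,bru_exception
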