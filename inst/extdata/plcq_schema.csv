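question,column,risk_when,in_score4,text
1,q1,yes,TRUE,Are you concerned about the way your child talks?
2,q2,yes,TRUE,Do other people have difficulty understanding your child?
3,q3,no,FALSE,Does your child talk as well as other children of the same age?
4,q4,yes,FALSE,Does your child speak funny or weird?
5,q5,yes,TRUE,Has a family member/teacher commented that your child talks little or talks poorly?
6,q6,no,FALSE,Does your child understand most of what is said to him/her?
7,q7,yes,FALSE,Do you have to repeat what you say to your child more than to other children of the same age?
8,q8,yes,TRUE,"Compared to other children of the same age, does your child have difficulties understanding questions?"
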